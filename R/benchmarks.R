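## Replicated benchmark protocols: generated-data correlation, masked-unknown
## RMSE, the two-group rare-cell-type comparison, and noise robustness on
## read-level mixtures. These drive both the test suite and the acceptance
## script.

.replicateSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^30, 2 * n)
}

#' Generated-data correlation benchmark
#'
#' Repeatedly simulates model-faithful data (25 cell types, 6000 regions, one
#' individual, Poisson(10) depth by default), fits the requested model with
#' multiple restarts, and records the Pearson correlation between estimated
#' and true proportions per replicate.
#'
#' @param nReplicates Number of replicates (default 50).
#' @param model \code{"celfeer"} or \code{"celfie"}.
#' @param seed Master seed; replicate data and fits use seeds derived from it.
#' @param nCellTypes,nRegions,nIndividuals,depthMean Design parameters.
#' @param nRestarts EM restarts per fit (default 10).
#' @return List with \code{r} (per-replicate correlations), \code{mean} and
#'   \code{sd}.
#' @export
runGeneratedBenchmark <- function(nReplicates = 50L,
                                  model = c("celfeer", "celfie"), seed = 1L,
                                  nCellTypes = 25L, nRegions = 6000L,
                                  nIndividuals = 1L, depthMean = 10,
                                  nRestarts = 10L) {
  model <- match.arg(model)
  seeds <- .replicateSeeds(seed, nReplicates)
  r <- vapply(seq_len(nReplicates), function(rep) {
    simSeed <- seeds[2 * rep - 1]
    fitSeed <- seeds[2 * rep]
    if (model == "celfeer") {
      sim <- simulateGeneratedData(nCellTypes, nRegions, nIndividuals,
        depthMean,
        seed = simSeed
      )
      fit <- fitCelfeer(sim$x, sim$y, nRestarts = nRestarts, seed = fitSeed)
    } else {
      sim <- simulateCelfieData(nCellTypes, nRegions, nIndividuals,
        depthMean,
        seed = simSeed
      )
      fit <- fitCelfie(sim$counts, nRestarts = nRestarts, seed = fitSeed)
    }
    mean(vapply(seq_len(nIndividuals), function(n) {
      pearsonR(
        as.numeric(cellTypeProportions(fit)[n, ]),
        as.numeric(sim$alphaTrue[n, ])
      )
    }, numeric(1)))
  }, numeric(1))
  list(r = r, mean = mean(r), sd = stats::sd(r))
}

#' Masked-unknown RMSE benchmark
#'
#' Runs the masked-unknown design (1000 regions, 10 cell types, 10
#' individuals, depth 10; unknown truth clipped Normal(0.2, 0.1)) and returns
#' the RMSE of the unknown cell type's estimated proportion across
#' individuals.
#'
#' @param model \code{"celfeer"} or \code{"celfie"}.
#' @param seed Master seed.
#' @param nRestarts EM restarts (default 10).
#' @param ... Passed to \code{\link{simulateUnknownExperiment}}.
#' @return List with \code{rmse}, the per-individual \code{estimate} and
#'   \code{truth}.
#' @export
runUnknownBenchmark <- function(model = c("celfeer", "celfie"), seed = 1L,
                                nRestarts = 10L, ...) {
  model <- match.arg(model)
  seeds <- .replicateSeeds(seed, 1L)
  sim <- simulateUnknownExperiment(model = model, seed = seeds[1], ...)
  fit <- if (model == "celfeer") {
    fitCelfeer(sim$x, sim$y, nRestarts = nRestarts, seed = seeds[2])
  } else {
    fitCelfie(sim$counts, nRestarts = nRestarts, seed = seeds[2])
  }
  est <- cellTypeProportions(fit)[, sim$unknownIndex]
  truth <- sim$alphaTrue[, sim$unknownIndex]
  list(rmse = rmse(est, truth), estimate = est, truth = truth)
}

#' Two-group rare-cell-type benchmark
#'
#' Replicates the rare-cell design (first cell type at proportion 0.01 in
#' group A, absent in group B) and fits both models on the same truths,
#' recording each model's estimated rare-type proportion per individual and
#' replicate, plus per-individual pooled-variance t tests comparing the two
#' models' replicate estimates.
#'
#' @param nReplicates Number of replicates (default 50).
#' @param seed Master seed.
#' @param nRestarts EM restarts (default 10).
#' @return List with \code{group} (factor A/B per individual), per-model
#'   matrices \code{celfeer} and \code{celfie} (replicates x individuals) of
#'   rare-type estimates, per-model group means \code{meanA}/\code{meanB},
#'   \code{methodComparisonP} (per-individual p values comparing the two
#'   models' replicate estimates) and \code{groupDifferenceP} (per-model
#'   p values comparing group A and B mean estimates).
#' @export
runRareBenchmark <- function(nReplicates = 50L, seed = 1L, nRestarts = 10L) {
  seeds <- .replicateSeeds(seed, nReplicates)
  estR <- matrix(NA_real_, nReplicates, 10)
  estC <- matrix(NA_real_, nReplicates, 10)
  group <- NULL
  for (rep in seq_len(nReplicates)) {
    simSeed <- seeds[2 * rep - 1]
    fitSeed <- seeds[2 * rep]
    simR <- simulateTwoGroupRare(model = "celfeer", seed = simSeed)
    simC <- simulateTwoGroupRare(model = "celfie", seed = simSeed)
    group <- simR$group
    fitR <- fitCelfeer(simR$x, simR$y, nRestarts = nRestarts, seed = fitSeed)
    fitC <- fitCelfie(simC$counts, nRestarts = nRestarts, seed = fitSeed)
    estR[rep, ] <- cellTypeProportions(fitR)[, simR$rareIndex]
    estC[rep, ] <- cellTypeProportions(fitC)[, simC$rareIndex]
  }
  pvals <- vapply(seq_len(10), function(n) {
    twoSampleT(estR[, n], estC[, n])$p.value
  }, numeric(1))
  # can either model tell the groups apart from the per-individual estimates?
  groupTest <- function(est) {
    means <- colMeans(est)
    twoSampleT(means[group == "A"], means[group == "B"])$p.value
  }
  list(
    group = group,
    celfeer = estR, celfie = estC,
    celfeerMeanA = mean(estR[, group == "A"]),
    celfeerMeanB = mean(estR[, group == "B"]),
    celfieMeanA = mean(estC[, group == "A"]),
    celfieMeanB = mean(estC[, group == "B"]),
    methodComparisonP = pvals,
    groupDifferenceP = c(
      celfeer = groupTest(estR),
      celfie = groupTest(estC)
    )
  )
}

#' Noise-robustness benchmark on read-level mixtures
#'
#' Builds read-level per-cell-type data with distinct methylation profiles,
#' mixes them at random proportions with coverage normalisation, flips CpG
#' states with each probability in \code{pValues}, and records the
#' correlation between estimated and true proportions.
#'
#' @param pValues Flip probabilities (default the benchmark grid
#'   0, 1/100, 1/30, 1/10).
#' @param nReplicates Replicates per probability (default 8).
#' @param seed Master seed.
#' @param nCellTypes,nWindows,coverage Design size (defaults 5, 150, 30).
#' @param nRestarts EM restarts (default 10).
#' @return List with \code{p}, matrix \code{r} (replicates x probabilities)
#'   and \code{meanR}.
#' @export
runNoiseBenchmark <- function(pValues = c(0, 1 / 100, 1 / 30, 1 / 10),
                              nReplicates = 8L, seed = 1L, nCellTypes = 5L,
                              nWindows = 150L, coverage = 30,
                              nRestarts = 10L) {
  wins <- makeWindows(stats::setNames(nWindows * 500L, "chr1"))
  r <- matrix(NA_real_, nReplicates, length(pValues))
  set.seed(seed)
  repSeeds <- sample.int(2^30, nReplicates)
  for (rep in seq_len(nReplicates)) {
    set.seed(repSeeds[rep])
    theta <- matrix(stats::runif(nCellTypes * nWindows), nCellTypes)
    refReads <- lapply(seq_len(nCellTypes), function(t) {
      simulateReads(theta[t, ], wins, meanDepth = coverage)
    })
    names(refReads) <- paste0("ct", seq_len(nCellTypes))
    inputReads <- lapply(seq_len(nCellTypes), function(t) {
      simulateReads(theta[t, ], wins, meanDepth = coverage)
    })
    props <- stats::runif(nCellTypes)
    props <- props / sum(props)
    mixed <- mixReads(inputReads, props,
      coverageFactor = coverage,
      nRegions = nWindows
    )
    y <- aggregateReference(refReads, wins)
    for (k in seq_along(pValues)) {
      noisy <- injectNoise(mixed, pValues[k])
      x <- binReads(noisy, wins)
      fit <- fitCelfeer(x, y, nRestarts = nRestarts, seed = repSeeds[rep])
      r[rep, k] <- pearsonR(as.numeric(cellTypeProportions(fit)), props)
    }
  }
  list(p = pValues, r = r, meanR = colMeans(r))
}
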
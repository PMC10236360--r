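## Synthetic data generators mirroring the benchmarking designs: model-
## faithful generated data (categorical/multinomial for the read-average
## model, Bernoulli/binomial for the CpG-count baseline), the two-group
## rare-cell-type design, the masked-unknown design, read-level simulation,
## mixture construction with coverage normalisation, and CpG-flip noise.

## vectorised multinomial sampling: one draw per row of `prob`, trial counts
## in `size`; sequential binomial thinning keeps everything vectorised
.rMultinomVec <- function(size, prob) {
  prob <- rbind(prob)
  k <- nrow(prob)
  nI <- ncol(prob)
  stopifnot(length(size) == k)
  out <- matrix(0L, k, nI)
  rem <- as.integer(size)
  pLeft <- rep(1, k)
  for (i in seq_len(nI - 1L)) {
    pi <- ifelse(pLeft > 1e-12, pmin(pmax(prob[, i] / pLeft, 0), 1), 1)
    draw <- stats::rbinom(k, rem, pi)
    out[, i] <- draw
    rem <- rem - draw
    pLeft <- pLeft - prob[, i]
  }
  out[, nI] <- rem
  out
}

## floor + Bernoulli on the fractional part: integer counts, exact expectation
.stochasticRound <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

## uniform proportions, rows normalised to 1
.runifProportions <- function(n, t) {
  .normalizeRows(matrix(stats::runif(n * t), n, t))
}

## symmetric Dirichlet draws, one row per (t, m) cell
.rDirichlet <- function(n, k, concentration = 1) {
  g <- matrix(stats::rgamma(n * k, shape = concentration), n, k)
  g / rowSums(g)
}

## input tensor given true alpha (N x T) and true beta (T x M x I):
## depth ~ Poisson(depthMean) per (n, m); each read draws a cell type from
## alpha_n and a bin from beta_tm
.generateReadInput <- function(alphaTrue, betaTrue, depthMean) {
  nN <- nrow(alphaTrue)
  nT <- dim(betaTrue)[1]
  nM <- dim(betaTrue)[2]
  nI <- dim(betaTrue)[3]
  x <- array(0, c(nN, nM, nI))
  for (n in seq_len(nN)) {
    depth <- stats::rpois(nM, depthMean)
    byType <- .rMultinomVec(depth, matrix(alphaTrue[n, ],
      nrow = nM, ncol = nT, byrow = TRUE
    ))
    for (t in seq_len(nT)) {
      x[n, , ] <- x[n, , ] +
        .rMultinomVec(byType[, t], matrix(betaTrue[t, , ], nM, nI))
    }
  }
  x
}

## reference tensor: depth ~ Poisson(depthMean), counts ~ Multinomial(beta_tm)
.generateReadReference <- function(betaTrue, depthMean) {
  nT <- dim(betaTrue)[1]
  nM <- dim(betaTrue)[2]
  nI <- dim(betaTrue)[3]
  y <- array(0, c(nT, nM, nI))
  for (t in seq_len(nT)) {
    depth <- stats::rpois(nM, depthMean)
    y[t, , ] <- .rMultinomVec(depth, matrix(betaTrue[t, , ], nM, nI))
  }
  y
}

#' Generate model-faithful read-average data
#'
#' Draws data exactly under the model assumptions: true proportions uniform
#' (normalised) per individual, true bin distributions symmetric
#' Dirichlet(\code{betaConcentration}) per cell type and region, per-region
#' read depth Poisson, each read's cell type categorical in the proportions
#' and its bin categorical in the cell type's distribution; reference counts
#' multinomial at Poisson depth.
#'
#' @param nCellTypes,nRegions,nIndividuals Problem dimensions (defaults 25,
#'   6000, 1 -- the generated-data benchmark design).
#' @param depthMean Poisson mean read depth per region (default 10).
#' @param seed Integer seed.
#' @param betaConcentration Dirichlet concentration of the true bin
#'   distributions (default 1).
#' @return List with \code{x} (\code{ReadCountTensor}), \code{y}
#'   (\code{ReferenceTensor}), \code{alphaTrue} and \code{betaTrue}.
#' @export
#' @examples
#' sim <- simulateGeneratedData(nCellTypes = 3, nRegions = 20, seed = 1)
#' rowSums(sim$alphaTrue)
simulateGeneratedData <- function(nCellTypes = 25L, nRegions = 6000L,
                                  nIndividuals = 1L, depthMean = 10,
                                  seed = 1L, betaConcentration = 1) {
  set.seed(seed)
  alphaTrue <- .runifProportions(nIndividuals, nCellTypes)
  betaTrue <- array(
    .rDirichlet(nCellTypes * nRegions, 5L, betaConcentration),
    c(nCellTypes, nRegions, 5L)
  )
  x <- .generateReadInput(alphaTrue, betaTrue, depthMean)
  y <- .generateReadReference(betaTrue, depthMean)
  list(
    x = ReadCountTensor(x), y = ReferenceTensor(y),
    alphaTrue = alphaTrue, betaTrue = betaTrue
  )
}

#' Generate model-faithful CpG-count data
#'
#' Binomial analogue of \code{\link{simulateGeneratedData}}: true methylation
#' fractions uniform on [0, 1], reads methylated with the fraction of their
#' cell type of origin, reference counts binomial at Poisson depth.
#'
#' @inheritParams simulateGeneratedData
#' @return List with \code{counts} (\code{CpGCounts}), \code{alphaTrue} and
#'   \code{betaTrue} (cell type x region methylation fractions).
#' @export
simulateCelfieData <- function(nCellTypes = 25L, nRegions = 6000L,
                               nIndividuals = 1L, depthMean = 10, seed = 1L) {
  set.seed(seed)
  alphaTrue <- .runifProportions(nIndividuals, nCellTypes)
  betaTrue <- matrix(stats::runif(nCellTypes * nRegions),
    nCellTypes, nRegions
  )
  sim <- .generateCelfieFromTruth(alphaTrue, betaTrue, depthMean)
  list(counts = sim, alphaTrue = alphaTrue, betaTrue = betaTrue)
}

.generateCelfieFromTruth <- function(alphaTrue, betaTrue, depthMean) {
  nN <- nrow(alphaTrue)
  nT <- nrow(betaTrue)
  nM <- ncol(betaTrue)
  xMeth <- matrix(0, nN, nM)
  xDepth <- matrix(0, nN, nM)
  for (n in seq_len(nN)) {
    depth <- stats::rpois(nM, depthMean)
    byType <- .rMultinomVec(depth, matrix(alphaTrue[n, ],
      nrow = nM, ncol = nT, byrow = TRUE
    ))
    meth <- 0
    for (t in seq_len(nT)) {
      meth <- meth + stats::rbinom(nM, byType[, t], betaTrue[t, ])
    }
    xMeth[n, ] <- meth
    xDepth[n, ] <- depth
  }
  yDepth <- matrix(stats::rpois(nT * nM, depthMean), nT, nM)
  yMeth <- matrix(stats::rbinom(nT * nM, as.vector(yDepth), as.vector(betaTrue)),
    nT, nM
  )
  CpGCounts(xMeth = xMeth, xDepth = xDepth, yMeth = yMeth, yDepth = yDepth)
}

## true proportions of the two-group rare design: the first cell type has
## proportion `rareProportion` in group A and 0 in group B before the joint
## normalisation; the remaining types are uniform on backgroundRange
.rareProportions <- function(nCellTypes, groupSize, rareProportion,
                             backgroundRange) {
  nN <- 2L * groupSize
  alpha <- matrix(0, nN, nCellTypes)
  for (n in seq_len(nN)) {
    bg <- stats::runif(nCellTypes - 1L, backgroundRange[1], backgroundRange[2])
    rare <- if (n <= groupSize) rareProportion else 0
    v <- c(rare, bg)
    alpha[n, ] <- v / sum(v)
  }
  alpha
}

#' Two-group rare-cell-type design
#'
#' Ten cell types over 1000 regions by default; the first cell type is
#' present at proportion 0.01 in the five group-A individuals and absent in
#' the five group-B individuals, the other nine have proportions uniform on
#' [0.5, 1], all jointly normalised to sum to one.
#'
#' @param nCellTypes,nRegions,groupSize,depthMean Design parameters.
#' @param rareProportion Pre-normalisation proportion of the rare type in
#'   group A (default 0.01).
#' @param backgroundRange Range of the background proportions (default
#'   c(0.5, 1)).
#' @param model \code{"celfeer"} (read-average data) or \code{"celfie"}
#'   (CpG-count data).
#' @param seed Integer seed.
#' @param betaConcentration Dirichlet concentration (read-average model only).
#' @return List with the dataset (\code{x}/\code{y} or \code{counts}),
#'   \code{alphaTrue}, \code{group} (factor A/B) and \code{rareIndex} (1).
#' @export
simulateTwoGroupRare <- function(nCellTypes = 10L, nRegions = 1000L,
                                 groupSize = 5L, depthMean = 10,
                                 rareProportion = 0.01,
                                 backgroundRange = c(0.5, 1),
                                 model = c("celfeer", "celfie"), seed = 1L,
                                 betaConcentration = 1) {
  model <- match.arg(model)
  set.seed(seed)
  alphaTrue <- .rareProportions(
    nCellTypes, groupSize, rareProportion, backgroundRange
  )
  group <- factor(rep(c("A", "B"), each = groupSize))
  if (model == "celfeer") {
    betaTrue <- array(
      .rDirichlet(nCellTypes * nRegions, 5L, betaConcentration),
      c(nCellTypes, nRegions, 5L)
    )
    out <- list(
      x = ReadCountTensor(.generateReadInput(alphaTrue, betaTrue, depthMean)),
      y = ReferenceTensor(.generateReadReference(betaTrue, depthMean))
    )
  } else {
    betaTrue <- matrix(stats::runif(nCellTypes * nRegions),
      nCellTypes, nRegions
    )
    out <- list(counts = .generateCelfieFromTruth(alphaTrue, betaTrue, depthMean))
  }
  c(out, list(
    alphaTrue = alphaTrue, betaTrue = betaTrue, group = group,
    rareIndex = 1L
  ))
}

#' Masked-unknown design
#'
#' The last cell type is treated as unknown: its true proportion is drawn per
#' individual from Normal(\code{unknownMean}, \code{unknownSd}) clipped to
#' [0, 1], the other proportions are uniform scaled to the remaining mass,
#' and its reference row is zeroed before fitting.
#'
#' @param nCellTypes,nRegions,nIndividuals,depthMean Design parameters
#'   (defaults 10, 1000, 10, 10).
#' @param unknownMean,unknownSd Clipped-normal parameters of the unknown
#'   proportion (defaults 0.2, 0.1).
#' @param model \code{"celfeer"} or \code{"celfie"}.
#' @param seed Integer seed.
#' @param betaConcentration Dirichlet concentration (read-average model only).
#' @return List with the masked dataset, \code{alphaTrue},
#'   \code{unknownIndex} (= \code{nCellTypes}) and the truths.
#' @export
simulateUnknownExperiment <- function(nCellTypes = 10L, nRegions = 1000L,
                                      nIndividuals = 10L, depthMean = 10,
                                      unknownMean = 0.2, unknownSd = 0.1,
                                      model = c("celfeer", "celfie"),
                                      seed = 1L, betaConcentration = 1) {
  model <- match.arg(model)
  set.seed(seed)
  u <- pmin(pmax(stats::rnorm(nIndividuals, unknownMean, unknownSd), 0), 1)
  alphaTrue <- matrix(0, nIndividuals, nCellTypes)
  for (n in seq_len(nIndividuals)) {
    known <- stats::runif(nCellTypes - 1L)
    alphaTrue[n, ] <- c(known / sum(known) * (1 - u[n]), u[n])
  }
  if (model == "celfeer") {
    betaTrue <- array(
      .rDirichlet(nCellTypes * nRegions, 5L, betaConcentration),
      c(nCellTypes, nRegions, 5L)
    )
    y <- ReferenceTensor(.generateReadReference(betaTrue, depthMean))
    y <- maskUnknowns(y, 1L, append = FALSE)
    out <- list(
      x = ReadCountTensor(.generateReadInput(alphaTrue, betaTrue, depthMean)),
      y = y
    )
  } else {
    betaTrue <- matrix(stats::runif(nCellTypes * nRegions),
      nCellTypes, nRegions
    )
    cc <- .generateCelfieFromTruth(alphaTrue, betaTrue, depthMean)
    cc@yMeth[nCellTypes, ] <- 0
    cc@yDepth[nCellTypes, ] <- 0
    cc@unknownMask[nCellTypes] <- TRUE
    out <- list(counts = cc)
  }
  c(out, list(
    alphaTrue = alphaTrue, betaTrue = betaTrue,
    unknownIndex = as.integer(nCellTypes), unknownTrue = u
  ))
}

#' Simulate read-level data for one cell type
#'
#' Places reads uniformly within each region; every CpG on a read is
#' methylated independently with the region's methylation probability for
#' that cell type.
#'
#' @param methylationProb Numeric vector: per-region probability that a CpG
#'   is methylated.
#' @param regions \code{GRanges} of regions.
#' @param meanDepth Poisson mean number of reads per region (default 10).
#' @param cpgsPerRead CpGs covered by each read (default 5).
#' @param readLength Genomic span of a read in bp (default 100, truncated to
#'   the region).
#' @param seed Optional integer seed.
#' @return Read data.frame (chrom, start, end, states).
#' @export
simulateReads <- function(methylationProb, regions, meanDepth = 10,
                          cpgsPerRead = 5L, readLength = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(methylationProb) == length(regions))
  nPer <- stats::rpois(length(regions), meanDepth)
  region <- rep(seq_along(regions), nPer)
  n <- length(region)
  if (n == 0) {
    return(data.frame(
      chrom = character(0), start = integer(0),
      end = integer(0), states = character(0)
    ))
  }
  rStart <- BiocGenerics::start(regions)[region] - 1L
  rEnd <- BiocGenerics::end(regions)[region]
  len <- pmin(readLength, rEnd - rStart)
  start <- rStart + floor(stats::runif(n) * (rEnd - rStart - len + 1))
  states <- matrix(
    stats::rbinom(n * cpgsPerRead, 1L, rep(methylationProb[region], cpgsPerRead)),
    nrow = n
  )
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions))[region],
    start = as.integer(start),
    end = as.integer(start + len),
    states = apply(states, 1, paste, collapse = ""),
    stringsAsFactors = FALSE
  )
}

#' Mix per-cell-type reads at chosen proportions
#'
#' Normalises the cell types to a common read total (the mean total, or
#' \code{coverageFactor * nRegions} when a coverage target is given), scales
#' each by its mixing proportion (proportions are renormalised to sum to one)
#' with stochastic rounding, and pools the sampled reads. Sampling is without
#' replacement when enough reads are available, otherwise with replacement
#' and a warning.
#'
#' @param readsByCellType Named list of read data.frames.
#' @param proportions Non-negative mixing weights, one per cell type.
#' @param coverageFactor Optional target mean reads per region per cell type.
#' @param nRegions Number of regions (required with \code{coverageFactor}).
#' @param seed Optional integer seed.
#' @return Pooled read data.frame.
#' @export
mixReads <- function(readsByCellType, proportions, coverageFactor = NULL,
                     nRegions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(proportions) == length(readsByCellType))
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (sum(proportions) <= 0) stop("proportions must not be all zero")
  proportions <- proportions / sum(proportions)
  totals <- vapply(readsByCellType, nrow, integer(1))
  base <- if (is.null(coverageFactor)) {
    mean(totals)
  } else {
    if (is.null(nRegions)) stop("nRegions is required with coverageFactor")
    coverageFactor * nRegions
  }
  targets <- .stochasticRound(base * proportions)
  picked <- lapply(seq_along(readsByCellType), function(t) {
    k <- targets[t]
    if (k == 0) return(NULL)
    reads <- readsByCellType[[t]]
    if (k > nrow(reads)) {
      warning(sprintf(
        "cell type %d: sampling %d reads from %d with replacement",
        t, k, nrow(reads)
      ))
      reads[sample.int(nrow(reads), k, replace = TRUE), , drop = FALSE]
    } else {
      reads[sample.int(nrow(reads), k), , drop = FALSE]
    }
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Mix per-cell-type count tensors at chosen proportions
#'
#' Count-level analogue of \code{\link{mixReads}} for pre-binned data: each
#' cell type's region x bin counts are rescaled to the common total (and
#' optional coverage target), multiplied by its proportion, stochastically
#' rounded, and summed into a single-individual input tensor.
#'
#' @param countsByCellType List of region x bin count matrices (or a
#'   \code{ReferenceTensor}).
#' @param proportions Non-negative mixing weights.
#' @param coverageFactor Optional target mean reads per region per cell type.
#' @param seed Optional integer seed.
#' @return A \code{ReadCountTensor} with one individual.
#' @export
mixCounts <- function(countsByCellType, proportions, coverageFactor = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(countsByCellType, "ReferenceTensor")) {
    arr <- counts(countsByCellType)
    countsByCellType <- lapply(
      seq_len(dim(arr)[1]),
      function(t) arr[t, , ]
    )
  }
  stopifnot(length(proportions) == length(countsByCellType))
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (sum(proportions) <= 0) stop("proportions must not be all zero")
  proportions <- proportions / sum(proportions)
  totals <- vapply(countsByCellType, sum, numeric(1))
  nM <- nrow(countsByCellType[[1]])
  base <- if (is.null(coverageFactor)) mean(totals) else coverageFactor * nM
  mixed <- 0
  for (t in seq_along(countsByCellType)) {
    if (totals[t] <= 0) next
    expected <- countsByCellType[[t]] * (base / totals[t]) * proportions[t]
    mixed <- mixed + matrix(.stochasticRound(as.vector(expected)), nM)
  }
  ReadCountTensor(array(mixed, c(1L, nM, ncol(countsByCellType[[1]]))))
}

#' Flip pooled CpG counts at random (count-mode noise)
#'
#' Binomial analogue of \code{\link{injectNoise}} for pre-pooled CpG count
#' matrices: each of the \code{meth} methylated measurements stays methylated
#' with probability \code{1 - p}, and each unmethylated measurement flips to
#' methylated with probability \code{p}; depths are unchanged.
#'
#' @param meth,depth Count matrices (methylated and total measurements).
#' @param p Flip probability in [0, 1].
#' @param seed Optional integer seed.
#' @return Matrix of noisy methylated counts.
#' @export
injectNoiseCounts <- function(meth, depth, p, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (any(meth > depth)) stop("meth cannot exceed depth")
  if (!is.null(seed)) set.seed(seed)
  kept <- stats::rbinom(length(meth), as.vector(meth), 1 - p)
  gained <- stats::rbinom(length(meth), as.vector(depth - meth), p)
  out <- meth
  out[] <- kept + gained
  out
}

#' Flip CpG methylation states at random
#'
#' Independently inverts each CpG state of each read with probability
#' \code{p}, emulating bisulfite conversion and sequencing noise.
#'
#' @param reads Read data.frame.
#' @param p Flip probability in [0, 1].
#' @param seed Optional integer seed.
#' @return Read data.frame with perturbed states.
#' @export
injectNoise <- function(reads, p, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (p == 0 || nrow(reads) == 0) return(reads)
  stateList <- strsplit(as.character(reads$states), "")
  lens <- lengths(stateList)
  flat <- as.integer(unlist(stateList))
  flip <- stats::runif(length(flat)) < p
  flat[flip] <- 1L - flat[flip]
  grp <- rep(seq_along(lens), lens)
  reads$states <- vapply(
    split(flat, grp), paste, character(1),
    collapse = ""
  )
  reads
}
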
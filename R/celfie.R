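## Beta-value (CpG count) EM baseline and NNLS regression baseline.
##
## The CpG-count model is the two-category special case of the read-average
## model: every CpG measurement is a Bernoulli draw (methylated or not) from
## the cell type of origin, and the reference counts are binomial. The same
## EM core therefore drives both models, with bins (unmethylated, methylated).

.celfieArrays <- function(counts) {
  stopifnot(is(counts, "CpGCounts"))
  nN <- nrow(counts@xMeth)
  nT <- nrow(counts@yMeth)
  nM <- ncol(counts@xMeth)
  x <- array(0, c(nN, nM, 2L), dimnames = list(
    rownames(counts@xMeth), colnames(counts@xMeth), c("u", "m")
  ))
  x[, , 1] <- counts@xDepth - counts@xMeth
  x[, , 2] <- counts@xMeth
  y <- array(0, c(nT, nM, 2L), dimnames = list(
    rownames(counts@yMeth), colnames(counts@yMeth), c("u", "m")
  ))
  y[, , 1] <- counts@yDepth - counts@yMeth
  y[, , 2] <- counts@yMeth
  list(x = x, y = y)
}

#' Fit the CpG-count (beta-value) EM baseline
#'
#' Expectation-maximization deconvolution on methylated/total CpG counts:
#' reads are Bernoulli in the methylation fraction of their cell type of
#' origin and the reference counts are binomial. Restart policy, convergence
#' rule and probability flooring are identical to \code{\link{fitCelfeer}}
#' so the two models are directly comparable.
#'
#' @param counts A \code{CpGCounts} object.
#' @inheritParams fitCelfeer
#' @return A \code{DeconvolutionFit} with \code{model = "celfie"};
#'   \code{\link{betaValues}} extracts the estimated methylation fractions.
#' @export
#' @examples
#' sim <- simulateCelfieData(
#'   nCellTypes = 3, nRegions = 50,
#'   nIndividuals = 2, depthMean = 20, seed = 1
#' )
#' fit <- fitCelfie(sim$counts, nRestarts = 2, seed = 1)
#' cellTypeProportions(fit)
fitCelfie <- function(counts, nRestarts = 10L, maxIter = 1000L, tol = 1e-4,
                      seed = 1L, freezeBeta = FALSE, alphaInit = NULL,
                      betaInit = NULL, trackLikelihood = FALSE) {
  arr <- .celfieArrays(counts)
  .fitCategorical(arr$x, arr$y, nRestarts, maxIter, tol, seed, freezeBeta,
    alphaInit, betaInit, trackLikelihood,
    model = "celfie",
    cellTypeNames = rownames(counts@yMeth),
    individualNames = rownames(counts@xMeth)
  )
}

#' Convert count matrices to beta values
#'
#' @param meth,depth Matrices of methylated and total counts.
#' @return Matrix of methylation fractions; cells with zero depth are
#'   \code{NA} (missing).
#' @export
#' @examples
#' countsToBeta(matrix(c(5, 0, 10)), matrix(c(10, 0, 10)))
countsToBeta <- function(meth, depth) {
  if (any(depth < 0)) stop("depth must be non-negative")
  ifelse(depth > 0, meth / depth, NA_real_)
}

#' Non-negative least squares deconvolution
#'
#' Per individual, solves \eqn{\min_w ||B^T w - b||_2} subject to
#' \eqn{w \ge 0}, where \eqn{B} is the reference beta-value matrix and
#' \eqn{b} the individual's beta values, then normalises the weights to sum
#' to one. Sites that are missing in the input or any reference cell type
#' (e.g. zero depth) are dropped per individual.
#'
#' @param inputBeta Individuals x regions matrix of beta values (may contain
#'   \code{NA} for zero-depth sites).
#' @param referenceBeta Cell types x regions matrix of reference beta values.
#' @return Individuals x cell types proportion matrix.
#' @export
#' @examples
#' ref <- rbind(a = c(1, 0, 0), b = c(0, 1, 0))
#' nnlsDeconvolve(rbind(0.5 * ref[1, ] + 0.5 * ref[2, ]), ref)
nnlsDeconvolve <- function(inputBeta, referenceBeta) {
  inputBeta <- rbind(inputBeta)
  refOk <- colSums(is.na(referenceBeta)) == 0
  if (!all(refOk)) {
    warning(sprintf("dropping %d site(s) missing in the reference", sum(!refOk)))
  }
  alpha <- matrix(NA_real_, nrow(inputBeta), nrow(referenceBeta),
    dimnames = list(rownames(inputBeta), rownames(referenceBeta))
  )
  for (n in seq_len(nrow(inputBeta))) {
    use <- refOk & !is.na(inputBeta[n, ])
    if (!any(use)) {
      warning("individual with no usable sites: proportions set uniform")
      alpha[n, ] <- 1 / nrow(referenceBeta)
      next
    }
    w <- pracma::lsqnonneg(
      t(referenceBeta[, use, drop = FALSE]),
      as.numeric(inputBeta[n, use])
    )$x
    if (sum(w) <= 0) {
      warning("all-zero NNLS solution: proportions set uniform")
      alpha[n, ] <- 1 / nrow(referenceBeta)
    } else {
      alpha[n, ] <- w / sum(w)
    }
  }
  alpha
}
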
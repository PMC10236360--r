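## Core mixture model: categorical read-average likelihood for the input,
## multinomial likelihood for the reference, closed-form EM updates.

.BETA_EPS <- 1e-10

.asInputArray <- function(x) {
  if (is(x, "ReadCountTensor")) x@counts else x
}

.asReferenceArray <- function(y) {
  if (is(y, "ReferenceTensor")) y@counts else y
}

.normalizeRows <- function(m) {
  s <- rowSums(m)
  zero <- s <= 0
  if (any(zero)) {
    m[zero, ] <- 1 / ncol(m)
    s[zero] <- 1
  }
  m / s
}

## floor every bin probability at eps and renormalise each (t, m) simplex
.floorBeta <- function(beta, eps = .BETA_EPS) {
  beta <- pmax(beta, eps)
  dims <- dim(beta)
  flat <- matrix(beta, nrow = dims[1] * dims[2], ncol = dims[3])
  array(flat / rowSums(flat), dims, dimnames = dimnames(beta))
}

#' Initialize EM parameters
#'
#' Mixing proportions are drawn i.i.d. uniform per individual and normalised
#' to sum to one; methylation bin distributions are initialised from the
#' reference proportions \eqn{Y_{tm.} / \sum_i Y_{tmi}}. Cell types without
#' reference reads at a region -- in particular masked (unknown) cell types --
#' start from the uniform distribution over the five bins. All probabilities
#' are floored at a small epsilon and renormalised so the posterior is always
#' defined.
#'
#' @param reference A \code{ReferenceTensor} or cell type x region x bin
#'   array of non-negative counts.
#' @param nIndividuals Number of individuals whose proportions are estimated.
#' @param seed Integer seed for the uniform draws (default 1).
#' @return List with elements \code{alpha} (individuals x cell types) and
#'   \code{beta} (cell types x regions x bins).
#' @export
#' @examples
#' y <- ReferenceTensor(array(rpois(2 * 3 * 5, 8), c(2, 3, 5)))
#' p <- initializeParameters(y, nIndividuals = 2, seed = 7)
#' rowSums(p$alpha)
initializeParameters <- function(reference, nIndividuals, seed = 1L) {
  y <- .asReferenceArray(reference)
  if (anyNA(y) || any(y < 0)) stop("reference counts must be non-negative")
  if (nIndividuals < 1) stop("nIndividuals must be >= 1")
  nT <- dim(y)[1]
  set.seed(seed)
  alpha <- .normalizeRows(matrix(stats::runif(nIndividuals * nT),
    nrow = nIndividuals, ncol = nT
  ))
  dims <- dim(y)
  depth <- matrix(rowSums(matrix(y, nrow = dims[1] * dims[2])),
    nrow = dims[1], ncol = dims[2]
  )
  flat <- matrix(y, nrow = dims[1] * dims[2])
  dvec <- as.vector(depth)
  beta <- flat / ifelse(dvec > 0, dvec, 1)
  beta[dvec == 0, ] <- 1 / dims[3]
  beta <- array(beta, dims, dimnames = dimnames(y))
  list(alpha = alpha, beta = .floorBeta(beta))
}

#' Posterior read-origin probabilities (E step)
#'
#' Computes the posterior probability that a read of individual \code{n} at
#' region \code{m} with read-average bin \code{i} originated from cell type
#' \code{t}: \eqn{p_{ntmi} = \alpha_{nt}\beta_{tmi} / \sum_k
#' \alpha_{nk}\beta_{kmi}}. Cells where the denominator is zero are set to 0
#' and counted in the \code{"zeroDenominator"} attribute.
#'
#' @param x \code{ReadCountTensor} or individuals x regions x bins array
#'   (only its shape is used).
#' @param alpha Individuals x cell types proportion matrix.
#' @param beta Cell types x regions x bins probability array.
#' @return Array of dimension individuals x cell types x regions x bins.
#' @export
eStep <- function(x, alpha, beta) {
  x <- .asInputArray(x)
  nN <- dim(x)[1]
  nT <- dim(beta)[1]
  nM <- dim(beta)[2]
  nI <- dim(beta)[3]
  if (dim(x)[2] != nM || dim(x)[3] != nI || ncol(alpha) != nT ||
    nrow(alpha) != nN) {
    stop("shape mismatch between input, alpha and beta")
  }
  p <- array(0, c(nN, nT, nM, nI))
  betaFlat <- matrix(beta, nrow = nT)
  zeros <- 0L
  for (n in seq_len(nN)) {
    num <- betaFlat * alpha[n, ] # recycles alpha over the cell-type axis
    denom <- colSums(num)
    ok <- denom > 0
    zeros <- zeros + sum(!ok)
    num[, ok] <- num[, ok, drop = FALSE] /
      rep(denom[ok], each = nT)
    num[, !ok] <- 0
    p[n, , , ] <- num
  }
  attr(p, "zeroDenominator") <- zeros
  p
}

#' Closed-form parameter updates (M step)
#'
#' Recomputes the mixing proportions from the posterior-weighted input counts
#' and the methylation bin distributions from the pooled posterior-weighted
#' input and reference counts. An individual without any reads has no
#' information about its proportions; its row is set uniform with a warning.
#'
#' @param x \code{ReadCountTensor} or input array.
#' @param y \code{ReferenceTensor} or reference array.
#' @param posterior Posterior array from \code{\link{eStep}} on the same data.
#' @return List with updated \code{alpha} and \code{beta}.
#' @export
mStep <- function(x, y, posterior) {
  x <- .asInputArray(x)
  y <- .asReferenceArray(y)
  nN <- dim(x)[1]
  nT <- dim(y)[1]
  nM <- dim(y)[2]
  nI <- dim(y)[3]
  alpha <- matrix(0, nN, nT)
  betaNum <- matrix(0, nrow = nT, ncol = nM * nI)
  for (n in seq_len(nN)) {
    pn <- matrix(posterior[n, , , ], nrow = nT) # T x (M*I)
    w <- pn * rep(as.vector(x[n, , ]), each = nT)
    alpha[n, ] <- rowSums(w)
    betaNum <- betaNum + w
  }
  if (any(rowSums(alpha) <= 0)) {
    warning("individual(s) with zero total reads: proportions set uniform")
  }
  alpha <- .normalizeRows(alpha)
  betaNum <- betaNum + nN * matrix(y, nrow = nT)
  beta <- array(betaNum, c(nT, nM, nI), dimnames = dimnames(y))
  flat <- matrix(beta, nrow = nT * nM)
  s <- rowSums(flat)
  flat[s <= 0, ] <- 1 / nI
  flat[s > 0, ] <- flat[s > 0, , drop = FALSE] / s[s > 0]
  beta <- array(flat, c(nT, nM, nI), dimnames = dimnames(y))
  list(alpha = alpha, beta = .floorBeta(beta))
}

#' Expected complete-data log-likelihood (Q function)
#'
#' Evaluates the EM objective: the expectation, under the posterior read-origin
#' probabilities, of the complete-data log-likelihood of input, latent origins
#' and reference. The data-only multinomial coefficient term of the reference
#' likelihood is included, so values are comparable across restarts on the
#' same data.
#'
#' @param x,y Input and reference tensors/arrays.
#' @param alpha,beta Current parameter values.
#' @param posterior Posterior array from \code{\link{eStep}}.
#' @return Scalar value of the objective.
#' @export
expectedLogLikelihood <- function(x, y, alpha, beta, posterior) {
  x <- .asInputArray(x)
  y <- .asReferenceArray(y)
  nN <- dim(x)[1]
  nT <- dim(y)[1]
  q <- 0
  logBeta <- ifelse(beta > 0, log(beta), 0)
  for (n in seq_len(nN)) {
    pn <- matrix(posterior[n, , , ], nrow = nT)
    px <- pn * rep(as.vector(x[n, , ]), each = nT)
    coefBeta <- px + matrix(y, nrow = nT)
    q <- q + sum(ifelse(coefBeta > 0, coefBeta * matrix(logBeta, nrow = nT), 0))
    logAlpha <- ifelse(alpha[n, ] > 0, log(alpha[n, ]), 0)
    q <- q + sum(rowSums(px) * logAlpha)
  }
  depth <- rowSums(matrix(y, nrow = nT * dim(y)[2]))
  q + nN * sum(lgamma(depth + 1) - rowSums(lgamma(matrix(y, nrow = nT * dim(y)[2]) + 1)))
}

## constant reference multinomial coefficient, identical across restarts
.logMultinomConst <- function(y, nN) {
  flat <- matrix(y, nrow = dim(y)[1] * dim(y)[2])
  nN * sum(lgamma(rowSums(flat) + 1) - rowSums(lgamma(flat + 1)))
}

.fitCategorical <- function(x, y, nRestarts, maxIter, tol, seed, freezeBeta,
                            alphaInit, betaInit, trackLikelihood, model,
                            cellTypeNames, individualNames) {
  nN <- dim(x)[1]
  nT <- dim(y)[1]
  nM <- dim(y)[2]
  if (nM < 1 || nT < 1) stop("need at least one region and one cell type")
  if (dim(x)[2] != nM || dim(x)[3] != dim(y)[3]) {
    stop("input and reference must share region and bin axes")
  }
  if (nRestarts < 1) stop("nRestarts must be >= 1")
  if (any(rowSums(matrix(x, nrow = nN)) == 0)) {
    warning("individual(s) with zero total reads: proportions set uniform")
  }
  storage.mode(x) <- "double"
  storage.mode(y) <- "double"
  const <- .logMultinomConst(y, nN)
  best <- NULL
  restartLL <- numeric(nRestarts)
  for (r in seq_len(nRestarts)) {
    init <- initializeParameters(y, nN, seed = seed + r)
    alpha0 <- if (is.null(alphaInit)) init$alpha else alphaInit
    beta0 <- if (is.null(betaInit)) init$beta else betaInit
    res <- .em_core(
      x, y, alpha0, beta0, as.integer(maxIter), tol, .BETA_EPS,
      freezeBeta, trackLikelihood
    )
    restartLL[r] <- res$loglik + const
    if (is.null(best) || restartLL[r] > best$loglik + const) {
      best <- res
      best$restart <- r
    }
  }
  if (!best$converged) {
    warning(sprintf(
      "EM did not converge within %d iterations (best restart %d)",
      maxIter, best$restart
    ))
  }
  alpha <- best$alpha
  dimnames(alpha) <- list(individualNames, cellTypeNames)
  beta <- best$beta
  dimnames(beta) <- dimnames(y)
  new("DeconvolutionFit",
    alpha = alpha, beta = beta, logLik = best$loglik + const,
    nIterations = as.integer(best$n_iter),
    restartIndex = as.integer(best$restart),
    converged = best$converged, model = model,
    restartLogLik = restartLL,
    llTrace = if (trackLikelihood) best$ll_trace + const else numeric(0)
  )
}

#' Fit the read-average deconvolution model
#'
#' Runs the EM algorithm from multiple random initialisations and returns the
#' restart with the highest log-likelihood. Convergence is declared when the
#' largest absolute change in any mixing proportion between consecutive
#' iterations drops below \code{tol}.
#'
#' @param x \code{ReadCountTensor} (or array) of input read-average counts.
#' @param y \code{ReferenceTensor} (or array) of reference counts; rows of
#'   zeros denote unknown cell types estimated from the input alone (see
#'   \code{\link{maskUnknowns}}).
#' @param nRestarts Number of independent EM restarts (default 10).
#' @param maxIter Maximum EM iterations per restart (default 1000).
#' @param tol Convergence threshold on \code{max |delta alpha|}
#'   (default 1e-4).
#' @param seed Master seed; restart \code{r} uses \code{seed + r}.
#' @param freezeBeta If \code{TRUE}, the methylation distributions stay at
#'   their initialisation and only the proportions are optimised.
#' @param alphaInit,betaInit Optional explicit initial values; when supplied
#'   they are used for every restart, making the fit deterministic.
#' @param trackLikelihood If \code{TRUE}, records the log-likelihood after
#'   every iteration of the winning restart (slower; for diagnostics).
#' @return A \code{DeconvolutionFit}. The log-likelihood is the marginal
#'   observed-data log-likelihood including the reference term.
#' @export
#' @examples
#' sim <- simulateGeneratedData(
#'   nCellTypes = 3, nRegions = 50,
#'   nIndividuals = 2, depthMean = 20, seed = 1
#' )
#' fit <- fitCelfeer(sim$x, sim$y, nRestarts = 2, seed = 1)
#' cellTypeProportions(fit)
fitCelfeer <- function(x, y, nRestarts = 10L, maxIter = 1000L, tol = 1e-4,
                       seed = 1L, freezeBeta = FALSE, alphaInit = NULL,
                       betaInit = NULL, trackLikelihood = FALSE) {
  xa <- .asInputArray(x)
  ya <- .asReferenceArray(y)
  cellTypeNames <- dimnames(ya)[[1]]
  if (is.null(cellTypeNames)) {
    cellTypeNames <- paste0("celltype_", seq_len(dim(ya)[1]))
  }
  indNames <- dimnames(xa)[[1]]
  if (is.null(indNames)) indNames <- paste0("individual_", seq_len(dim(xa)[1]))
  .fitCategorical(xa, ya, nRestarts, maxIter, tol, seed, freezeBeta,
    alphaInit, betaInit, trackLikelihood,
    model = "celfeer",
    cellTypeNames = cellTypeNames, individualNames = indNames
  )
}

#' Mask cell types as unknown
#'
#' Appends all-zero reference rows (named \code{unknown_1, ...}) flagged as
#' unknown, or zeroes the last existing rows when \code{append = FALSE}. The
#' model then estimates these cell types' methylation distributions from the
#' input data alone, starting from the uniform bin distribution.
#'
#' @param y A \code{ReferenceTensor}.
#' @param nUnknown Number of unknown cell types (>= 0).
#' @param append If \code{TRUE} (default) add new rows; otherwise zero out the
#'   last \code{nUnknown} existing cell types.
#' @return A \code{ReferenceTensor} with updated counts and mask.
#' @export
#' @examples
#' y <- ReferenceTensor(array(3, c(2, 4, 5)))
#' maskUnknowns(y, 1)
maskUnknowns <- function(y, nUnknown, append = TRUE) {
  stopifnot(is(y, "ReferenceTensor"))
  if (nUnknown < 0) stop("nUnknown must be >= 0")
  if (nUnknown == 0) return(y)
  cts <- y@counts
  d <- dim(cts)
  if (append) {
    newCounts <- array(0, c(d[1] + nUnknown, d[2], d[3]))
    newCounts[seq_len(d[1]), , ] <- cts
    dimnames(newCounts) <- list(
      c(dimnames(cts)[[1]], paste0("unknown_", seq_len(nUnknown))),
      dimnames(cts)[[2]], dimnames(cts)[[3]]
    )
    mask <- c(y@unknownMask, rep(TRUE, nUnknown))
  } else {
    if (nUnknown > d[1]) stop("cannot mask more cell types than present")
    idx <- seq(d[1] - nUnknown + 1L, d[1])
    newCounts <- cts
    newCounts[idx, , ] <- 0
    mask <- y@unknownMask
    mask[idx] <- TRUE
  }
  new("ReferenceTensor", counts = newCounts, unknownMask = mask,
    metadata = y@metadata)
}
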
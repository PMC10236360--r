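## Scoring utilities used across the benchmarking designs.

#' Pearson correlation between estimated and true proportions
#'
#' @param est,truth Numeric vectors of equal length (>= 2).
#' @return Pearson product-moment correlation; \code{NA} with a warning when
#'   either vector is constant.
#' @export
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))
pearsonR <- function(est, truth) {
  if (length(est) != length(truth)) stop("vectors must have equal length")
  if (length(est) < 2) stop("need at least two values")
  if (stats::sd(est) == 0 || stats::sd(truth) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(est, truth)
}

#' Root mean squared error
#'
#' @param est,truth Numeric vectors of equal length.
#' @return \code{sqrt(mean((est - truth)^2))}.
#' @export
#' @examples
#' rmse(c(0.3, 0.4), c(0, 0))
rmse <- function(est, truth) {
  if (length(est) != length(truth)) stop("vectors must have equal length")
  sqrt(mean((est - truth)^2))
}

#' Pooled-variance two-sample t test
#'
#' Student's t test with equal-variance pooling, so the degrees of freedom are
#' \code{n1 + n2 - 2}.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return List with \code{statistic}, \code{df} and \code{p.value}
#'   (two-sided). \code{NA}s with a warning when the pooled variance is zero.
#' @export
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
twoSampleT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least two values per group")
  df <- length(a) + length(b) - 2L
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warning("zero pooled variance: t statistic undefined")
    return(list(statistic = NA_real_, df = df, p.value = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

#' Summarise an experiment's replicate scores
#'
#' @param r Numeric vector of per-replicate correlation values (optional).
#' @param rmse Numeric vector of per-replicate RMSE values (optional).
#' @return List with per-metric values, mean and standard deviation.
#' @export
experimentReport <- function(r = NULL, rmse = NULL) {
  summarise <- function(v) {
    if (is.null(v)) {
      return(NULL)
    }
    list(values = v, mean = mean(v), sd = stats::sd(v))
  }
  out <- list(r = summarise(r), rmse = summarise(rmse))
  out[!vapply(out, is.null, logical(1))]
}
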
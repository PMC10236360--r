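#' @import methods
#' @importFrom S4Vectors metadata
#' @importClassesFrom S4Vectors Annotated
NULL

## The five read-average bins shared by all read-resolution containers.
.BIN_CENTERS <- c(0, 0.25, 0.5, 0.75, 1)

#' Read-average bin centers
#'
#' The discretisation grid used for per-read average methylation. A read
#' average (methylated CpGs / CpGs on the read) is rounded to the closest of
#' these five values before being one-hot encoded and summed per region.
#'
#' @return Numeric vector \code{c(0, 0.25, 0.5, 0.75, 1)}.
#' @export
#' @examples
#' binCenters()
binCenters <- function() .BIN_CENTERS

setClass("ReadCountTensor",
  contains = "Annotated",
  representation(counts = "array")
)

setValidity("ReadCountTensor", function(object) {
  cts <- object@counts
  if (length(dim(cts)) != 3L) {
    return("counts must be a 3-d array (individual x region x bin)")
  }
  if (dim(cts)[3] != 5L) return("bin axis must have length 5")
  if (anyNA(cts) || any(cts < 0)) return("counts must be non-negative")
  dn <- dimnames(cts)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]])) {
    return("individual and region dimnames are required")
  }
  TRUE
})

setClass("ReferenceTensor",
  contains = "Annotated",
  representation(counts = "array", unknownMask = "logical")
)

setValidity("ReferenceTensor", function(object) {
  cts <- object@counts
  if (length(dim(cts)) != 3L) {
    return("counts must be a 3-d array (cell type x region x bin)")
  }
  if (dim(cts)[3] != 5L) return("bin axis must have length 5")
  if (anyNA(cts) || any(cts < 0)) return("counts must be non-negative")
  dn <- dimnames(cts)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]])) {
    return("cell type and region dimnames are required")
  }
  if (length(object@unknownMask) != dim(cts)[1]) {
    return("unknownMask must have one flag per cell type")
  }
  if (any(object@unknownMask)) {
    masked <- object@counts[object@unknownMask, , , drop = FALSE]
    if (any(masked != 0)) {
      return("cell types flagged unknown must have all-zero counts")
    }
  }
  TRUE
})

setClass("CpGCounts",
  contains = "Annotated",
  representation(
    xMeth = "matrix", xDepth = "matrix",
    yMeth = "matrix", yDepth = "matrix",
    unknownMask = "logical"
  )
)

setValidity("CpGCounts", function(object) {
  if (!identical(dim(object@xMeth), dim(object@xDepth))) {
    return("xMeth and xDepth must have identical dimensions")
  }
  if (!identical(dim(object@yMeth), dim(object@yDepth))) {
    return("yMeth and yDepth must have identical dimensions")
  }
  if (ncol(object@xMeth) != ncol(object@yMeth)) {
    return("input and reference must share the region axis")
  }
  if (any(object@xMeth < 0) || any(object@yMeth < 0)) {
    return("counts must be non-negative")
  }
  if (any(object@xMeth > object@xDepth) || any(object@yMeth > object@yDepth)) {
    return("methylated counts cannot exceed total depth")
  }
  if (length(object@unknownMask) != nrow(object@yMeth)) {
    return("unknownMask must have one flag per cell type")
  }
  TRUE
})

setClass("DeconvolutionFit",
  representation(
    alpha = "matrix", beta = "array", logLik = "numeric",
    nIterations = "integer", restartIndex = "integer",
    converged = "logical", model = "character",
    restartLogLik = "numeric", llTrace = "numeric"
  )
)

setValidity("DeconvolutionFit", function(object) {
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  if (any(object@alpha < -1e-8) || any(object@alpha > 1 + 1e-8)) {
    return("alpha entries must lie in [0, 1]")
  }
  if (any(abs(rowSums(object@alpha) - 1) > 1e-8)) {
    return("alpha rows must sum to 1")
  }
  TRUE
})

#' Read-average count tensor
#'
#' Container for the model input: per individual and marker region, the number
#' of reads falling in each of the five read-average bins.
#'
#' @param counts Integer/numeric array of dimension
#'   \code{individuals x regions x 5}, or for a single individual a
#'   \code{regions x 5} matrix.
#' @param regionIds Character vector of region identifiers (defaults to
#'   existing dimnames or \code{region_1, ...}).
#' @param individualIds Character vector of sample identifiers.
#' @return A \code{ReadCountTensor}.
#' @export
#' @examples
#' x <- ReadCountTensor(array(1, c(2, 3, 5)))
#' dim(counts(x))
ReadCountTensor <- function(counts, regionIds = NULL, individualIds = NULL) {
  if (is.matrix(counts)) counts <- array(counts, c(1L, dim(counts)))
  counts <- .nameTensor(counts, individualIds, regionIds, "individual")
  new("ReadCountTensor", counts = counts)
}

#' Reference methylation count tensor
#'
#' Container for the reference panel: per cell type and region, read counts
#' over the five read-average bins. Cell types flagged in \code{unknownMask}
#' carry all-zero counts and are estimated from the input alone.
#'
#' @param counts Array of dimension \code{cell types x regions x 5}.
#' @param regionIds,cellTypeIds Optional identifier vectors.
#' @param unknownMask Logical per-cell-type flag; defaults to all \code{FALSE}.
#' @return A \code{ReferenceTensor}.
#' @export
#' @examples
#' y <- ReferenceTensor(array(2, c(3, 4, 5)))
#' cellTypes(y)
ReferenceTensor <- function(counts, cellTypeIds = NULL, regionIds = NULL,
                            unknownMask = NULL) {
  counts <- .nameTensor(counts, cellTypeIds, regionIds, "celltype")
  if (is.null(unknownMask)) unknownMask <- rep(FALSE, dim(counts)[1])
  new("ReferenceTensor", counts = counts, unknownMask = unknownMask)
}

#' CpG count matrices for the beta-value baseline
#'
#' Input/reference container for the CpG-count model: methylated and total
#' read counts per individual (\code{x*}) and per reference cell type
#' (\code{y*}) at each site or pooled 500 bp region.
#'
#' @param xMeth,xDepth Individual x region matrices of methylated / total
#'   counts.
#' @param yMeth,yDepth Cell type x region matrices of methylated / total
#'   counts.
#' @param unknownMask Logical per-cell-type flag for masked cell types.
#' @return A \code{CpGCounts}.
#' @export
#' @examples
#' cc <- CpGCounts(
#'   xMeth = matrix(1, 1, 3), xDepth = matrix(2, 1, 3),
#'   yMeth = matrix(5, 2, 3), yDepth = matrix(10, 2, 3)
#' )
CpGCounts <- function(xMeth, xDepth, yMeth, yDepth, unknownMask = NULL) {
  fix <- function(m, pre) {
    m <- as.matrix(m)
    if (is.null(rownames(m))) rownames(m) <- paste0(pre, "_", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("region_", seq_len(ncol(m)))
    m
  }
  if (is.null(unknownMask)) unknownMask <- rep(FALSE, nrow(as.matrix(yMeth)))
  new("CpGCounts",
    xMeth = fix(xMeth, "individual"), xDepth = fix(xDepth, "individual"),
    yMeth = fix(yMeth, "celltype"), yDepth = fix(yDepth, "celltype"),
    unknownMask = unknownMask
  )
}

.nameTensor <- function(counts, firstIds, regionIds, firstPrefix) {
  stopifnot(length(dim(counts)) == 3L)
  dn <- dimnames(counts)
  if (is.null(dn)) dn <- vector("list", 3)
  if (!is.null(firstIds)) dn[[1]] <- firstIds
  if (!is.null(regionIds)) dn[[2]] <- regionIds
  if (is.null(dn[[1]])) dn[[1]] <- paste0(firstPrefix, "_", seq_len(dim(counts)[1]))
  if (is.null(dn[[2]])) dn[[2]] <- paste0("region_", seq_len(dim(counts)[2]))
  if (dim(counts)[3] == length(.BIN_CENTERS)) {
    dn[[3]] <- as.character(.BIN_CENTERS)
  } else {
    dn[3] <- list(NULL) # validity reports the bad bin axis
  }
  dimnames(counts) <- dn
  counts
}

## ---- accessors ----

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "ReadCountTensor", function(object, ...) object@counts)

#' @export
setMethod("counts", "ReferenceTensor", function(object, ...) object@counts)

setGeneric("regionIds", function(x) standardGeneric("regionIds"))
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
setGeneric("unknownMask", function(x) standardGeneric("unknownMask"))

#' @export
setMethod("regionIds", "ReadCountTensor", function(x) dimnames(x@counts)[[2]])
#' @export
setMethod("regionIds", "ReferenceTensor", function(x) dimnames(x@counts)[[2]])
#' @export
setMethod("regionIds", "CpGCounts", function(x) colnames(x@xMeth))
#' @export
setMethod("individualIds", "ReadCountTensor", function(x) dimnames(x@counts)[[1]])
#' @export
setMethod("individualIds", "CpGCounts", function(x) rownames(x@xMeth))
#' @export
setMethod("cellTypes", "ReferenceTensor", function(x) dimnames(x@counts)[[1]])
#' @export
setMethod("cellTypes", "CpGCounts", function(x) rownames(x@yMeth))
#' @export
setMethod("unknownMask", "ReferenceTensor", function(x) {
  stats::setNames(x@unknownMask, cellTypes(x))
})
#' @export
setMethod("unknownMask", "CpGCounts", function(x) {
  stats::setNames(x@unknownMask, cellTypes(x))
})

setGeneric("cellTypeProportions", function(x) standardGeneric("cellTypeProportions"))

#' Estimated cell type proportions
#'
#' @param x A \code{DeconvolutionFit}.
#' @return Individuals x cell types matrix of mixing proportions (rows sum
#'   to 1).
#' @export
setMethod("cellTypeProportions", "DeconvolutionFit", function(x) x@alpha)

setGeneric("methylationProfiles", function(x) standardGeneric("methylationProfiles"))

#' Estimated per-cell-type methylation distributions
#'
#' @param x A \code{DeconvolutionFit}.
#' @return For the read-average model, a cell type x region x 5 array of bin
#'   probabilities; for the CpG-count baseline a cell type x region x 2 array
#'   (unmethylated, methylated).
#' @export
setMethod("methylationProfiles", "DeconvolutionFit", function(x) x@beta)

setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Estimated methylation fractions of the CpG-count baseline
#'
#' @param x A \code{DeconvolutionFit} from \code{\link{fitCelfie}}.
#' @return Cell type x region matrix of methylation fractions.
#' @export
setMethod("betaValues", "DeconvolutionFit", function(x) {
  if (dim(x@beta)[3] != 2L) {
    stop("betaValues is defined for the two-category (CpG count) model")
  }
  x@beta[, , 2L]
})

#' @export
setMethod("logLik", "DeconvolutionFit", function(object, ...) object@logLik)

#' @export
setMethod("show", "ReadCountTensor", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "ReadCountTensor: %d individual(s) x %d region(s) x 5 bins (%s reads)\n",
    d[1], d[2], format(sum(object@counts), big.mark = ",")
  ))
})

#' @export
setMethod("show", "ReferenceTensor", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "ReferenceTensor: %d cell type(s) x %d region(s) x 5 bins, %d unknown\n",
    d[1], d[2], sum(object@unknownMask)
  ))
})

#' @export
setMethod("show", "CpGCounts", function(object) {
  cat(sprintf(
    "CpGCounts: %d individual(s), %d cell type(s), %d region(s)\n",
    nrow(object@xMeth), nrow(object@yMeth), ncol(object@xMeth)
  ))
})

#' @export
setMethod("show", "DeconvolutionFit", function(object) {
  cat(sprintf(
    "DeconvolutionFit (%s): %d individual(s) x %d cell type(s)\n",
    object@model, nrow(object@alpha), ncol(object@alpha)
  ))
  cat(sprintf(
    "  log-likelihood %.4f after %d iteration(s), restart %d, converged: %s\n",
    object@logLik, object@nIterations, object@restartIndex,
    object@converged
  ))
})
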
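## Readers and writers for the package's plain-text formats: read-level TSV,
## BED marker regions, binned count tensors, CpG count matrices, and fit
## output (proportions, methylation distributions, metadata sidecar).

#' Parse a read-level methylation TSV
#'
#' Expected columns (tab-separated, no header): chrom, start, end (0-based
#' half-open) and a methylation-state string over \{0,1\}, one character per
#' CpG on the read; an optional fifth column names the sample.
#'
#' @param path Input file.
#' @return Read data.frame (chrom, start, end, states[, sample]). Malformed
#'   lines raise an error naming the line number.
#' @export
parseReadFile <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(
      chrom = character(0), start = integer(0),
      end = integer(0), states = character(0)
    ))
  }
  dt <- data.table::fread(path,
    header = FALSE, sep = "\t",
    colClasses = "character", fill = TRUE, data.table = FALSE
  )
  if (nrow(dt) == 0) {
    return(data.frame(
      chrom = character(0), start = integer(0),
      end = integer(0), states = character(0)
    ))
  }
  if (ncol(dt) < 4) stop("read file needs at least 4 tab-separated columns")
  names(dt)[1:4] <- c("chrom", "start", "end", "states")
  if (ncol(dt) >= 5) names(dt)[5] <- "sample"
  dt$start <- suppressWarnings(as.integer(dt$start))
  dt$end <- suppressWarnings(as.integer(dt$end))
  bad <- which(grepl("[^01]", dt$states) | nchar(dt$states) == 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid methylation states on line(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start >= dt$end)
  if (length(bad) > 0) {
    stop(sprintf(
      "start must be < end on line(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  dt[, intersect(c("chrom", "start", "end", "states", "sample"), names(dt))]
}

#' Parse marker regions from BED
#'
#' Reads a BED file (0-based half-open), sorts the regions, and fails on
#' overlapping intervals. The BED name column, when present, becomes the
#' region names.
#'
#' @param path BED file (3 or more columns).
#' @return Sorted \code{GRanges}.
#' @export
parseRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- BiocGenerics::sort(gr)
  if (length(gr) > 1) {
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(ov) > 0) stop("regions in ", path, " overlap")
  }
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

## bin columns are suffixed .b0 .b25 .b50 .b75 .b100 (percent of the center)
.BIN_SUFFIX <- paste0("b", c(0, 25, 50, 75, 100))

.tensorToWide <- function(arr) {
  ## (first x region x bin) array -> region rows, first*bin columns; within a
  ## sample the bins are adjacent in bin order
  d <- dim(arr)
  wide <- matrix(aperm(arr, c(2, 3, 1)), nrow = d[2])
  colnames(wide) <- paste(
    rep(dimnames(arr)[[1]], each = d[3]),
    rep(.BIN_SUFFIX, d[1]),
    sep = "."
  )
  data.frame(region = dimnames(arr)[[2]], wide, check.names = FALSE)
}

.wideToTensor <- function(df) {
  region <- as.character(df$region)
  mat <- as.matrix(df[, -1, drop = FALSE])
  nm <- colnames(mat)
  if (!all(grepl("\\.b\\d+$", nm))) {
    stop("count TSV columns must be named <sample>.b<bin percent>")
  }
  first <- sub("\\.b\\d+$", "", nm)
  bin <- sub("^.*\\.(b\\d+)$", "\\1", nm)
  firstIds <- unique(first)
  arr <- array(0, c(length(firstIds), nrow(mat), length(.BIN_SUFFIX)))
  for (k in seq_along(firstIds)) {
    sel <- mat[, first == firstIds[k], drop = FALSE]
    arr[k, , ] <- sel[, match(.BIN_SUFFIX, bin[first == firstIds[k]]),
      drop = FALSE
    ]
  }
  dimnames(arr) <- list(firstIds, region, as.character(.BIN_CENTERS))
  arr
}

#' Write / read a read-average input tensor as TSV
#'
#' One row per region: the region id, then the five bin counts per individual
#' (columns named \code{<sample>.<bin>}, bin order 0, 0.25, 0.5, 0.75, 1).
#'
#' @param x A \code{ReadCountTensor}.
#' @param path Output / input file.
#' @return \code{writeCountsTsv}: the path, invisibly; \code{readCountsTsv}:
#'   a \code{ReadCountTensor}.
#' @export
writeCountsTsv <- function(x, path) {
  stopifnot(is(x, "ReadCountTensor"))
  utils::write.table(.tensorToWide(counts(x)), path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  arr <- .wideToTensor(df)
  ReadCountTensor(arr,
    regionIds = dimnames(arr)[[2]],
    individualIds = dimnames(arr)[[1]]
  )
}

#' Write / read a reference tensor as TSV
#'
#' Same layout as \code{\link{writeCountsTsv}} with cell types as samples;
#' all-zero cell types are flagged unknown on reading.
#'
#' @param y A \code{ReferenceTensor}.
#' @param path Output / input file.
#' @return \code{writeReferenceTsv}: the path, invisibly;
#'   \code{readReferenceTsv}: a \code{ReferenceTensor}.
#' @export
writeReferenceTsv <- function(y, path) {
  stopifnot(is(y, "ReferenceTensor"))
  utils::write.table(.tensorToWide(counts(y)), path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeReferenceTsv
#' @export
readReferenceTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  arr <- .wideToTensor(df)
  mask <- rowSums(matrix(arr, nrow = dim(arr)[1])) == 0
  ReferenceTensor(arr,
    cellTypeIds = dimnames(arr)[[1]],
    regionIds = dimnames(arr)[[2]], unknownMask = unname(mask)
  )
}

#' Write / read CpG count matrices as TSV
#'
#' One row per region: the region id, then repeating
#' \code{<sample>.meth} / \code{<sample>.depth} column pairs.
#'
#' @param meth,depth Sample x region matrices.
#' @param path Output / input file.
#' @return \code{writeMethDepthTsv}: the path, invisibly;
#'   \code{readMethDepthTsv}: list with \code{meth} and \code{depth}.
#' @export
writeMethDepthTsv <- function(meth, depth, path) {
  stopifnot(identical(dim(meth), dim(depth)))
  nS <- nrow(meth)
  wide <- matrix(0, ncol(meth), 2L * nS)
  wide[, seq(1, 2 * nS, by = 2)] <- t(meth)
  wide[, seq(2, 2 * nS, by = 2)] <- t(depth)
  nms <- rownames(meth)
  if (is.null(nms)) nms <- paste0("sample_", seq_len(nS))
  colnames(wide) <- paste(rep(nms, each = 2), c("meth", "depth"), sep = ".")
  rid <- colnames(meth)
  if (is.null(rid)) rid <- paste0("region_", seq_len(ncol(meth)))
  utils::write.table(data.frame(region = rid, wide, check.names = FALSE),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeMethDepthTsv
#' @export
readMethDepthTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  isMeth <- grepl("\\.meth$", colnames(mat))
  meth <- t(mat[, isMeth, drop = FALSE])
  depth <- t(mat[, !isMeth, drop = FALSE])
  rownames(meth) <- sub("\\.meth$", "", colnames(mat)[isMeth])
  rownames(depth) <- sub("\\.depth$", "", colnames(mat)[!isMeth])
  colnames(meth) <- colnames(depth) <- df$region
  list(meth = meth, depth = depth)
}

#' Write a fit to an output directory
#'
#' Writes \code{alpha.tsv} (individuals x cell types, unknowns named
#' \code{unknown_*}), \code{beta.tsv} (cell type, region, then one column per
#' bin) and \code{metadata.json} (model, seed, restart count and winning
#' index, iterations, convergence, per-restart and final log-likelihood, and
#' the run configuration).
#'
#' @param fit A \code{DeconvolutionFit}.
#' @param dir Output directory (created if missing).
#' @param config Optional named list recorded verbatim in the metadata.
#' @return The directory, invisibly.
#' @export
writeFit <- function(fit, dir, config = list()) {
  stopifnot(is(fit, "DeconvolutionFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  alpha <- cellTypeProportions(fit)
  utils::write.table(
    data.frame(individual = rownames(alpha), alpha, check.names = FALSE),
    file.path(dir, "alpha.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  beta <- methylationProfiles(fit)
  d <- dim(beta)
  flat <- matrix(aperm(beta, c(2, 1, 3)), nrow = d[1] * d[2])
  colnames(flat) <- paste0("bin_", dimnames(beta)[[3]])
  betaDf <- data.frame(
    cellType = rep(dimnames(beta)[[1]], each = d[2]),
    region = rep(dimnames(beta)[[2]], d[1]),
    flat, check.names = FALSE
  )
  utils::write.table(betaDf, file.path(dir, "beta.tsv"),
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  meta <- list(
    model = fit@model,
    logLik = fit@logLik,
    nIterations = fit@nIterations,
    restartIndex = fit@restartIndex,
    converged = fit@converged,
    restartLogLik = fit@restartLogLik,
    config = config
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read proportion estimates written by \code{\link{writeFit}}
#'
#' @param path \code{alpha.tsv} file.
#' @return Individuals x cell types matrix.
#' @export
readProportionsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
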
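## Read-level processing: read averages, 5-bin encoding, assignment of reads
## to 500 bp windows / marker regions.
##
## Reads are represented as a data.frame with columns chrom, start, end
## (0-based half-open) and states (a string over {0,1}, one character per CpG
## covered by the read). Regions are GRanges (1-based closed internally; BED
## input is converted by rtracklayer).

#' Average methylation of a read
#'
#' @param states Integer/numeric vector of 0/1 methylation calls, or a string
#'   such as \code{"101"}.
#' @param minCpgs Minimum number of CpG sites required (default 3); reads with
#'   fewer are discarded.
#' @return Fraction of methylated CpGs, or \code{NA} when the read has fewer
#'   than \code{minCpgs} sites.
#' @export
#' @examples
#' readAverage(c(1, 0, 0))
#' readAverage("10") # filtered
readAverage <- function(states, minCpgs = 3L) {
  if (is.character(states)) {
    states <- as.integer(strsplit(states, "")[[1]])
  }
  if (length(states) == 0 || !all(states %in% c(0, 1))) {
    stop("methylation states must be 0/1")
  }
  if (length(states) < minCpgs) return(NA_real_)
  mean(states)
}

## midpoints between consecutive bin centers; exact midpoints round up
.BIN_BREAKS <- c(0.125, 0.375, 0.625, 0.875)

#' Encode a read average as a bin index
#'
#' Rounds a read average to the closest of the five bin centers
#' \code{0, 0.25, 0.5, 0.75, 1}; exact midpoints between two centers round up
#' to the higher bin.
#'
#' @param avg Numeric vector of read averages in [0, 1].
#' @return Integer bin indices in 1..5 (1 = fully unmethylated).
#' @export
#' @examples
#' encodeRead(1 / 3) # bin 2, center 0.25
#' encodeRead(0.375) # midpoint rounds up to bin 3
encodeRead <- function(avg) {
  if (any(is.na(avg)) || any(avg < 0) || any(avg > 1)) {
    stop("read averages must lie in [0, 1]")
  }
  findInterval(avg, .BIN_BREAKS) + 1L
}

.validateReads <- function(reads) {
  stopifnot(is.data.frame(reads))
  need <- c("chrom", "start", "end", "states")
  if (!all(need %in% names(reads))) {
    stop("reads need columns chrom, start, end, states")
  }
  if (any(reads$start >= reads$end)) stop("read start must be < end")
  invisible(reads)
}

.validateRegions <- function(regions) {
  stopifnot(is(regions, "GRanges"))
  regions <- GenomicRanges::sort(regions)
  if (length(regions) > 1 &&
    any(S4Vectors::queryHits(GenomicRanges::findOverlaps(regions,
      drop.self = TRUE
    )) > 0)) {
    stop("regions must be non-overlapping")
  }
  regions
}

.regionLabels <- function(regions) {
  nm <- names(regions)
  if (!is.null(nm) && !anyNA(nm) && !any(nm == "")) return(nm)
  paste0(
    GenomicRanges::seqnames(regions), ":",
    GenomicRanges::start(regions) - 1L, "-", GenomicRanges::end(regions)
  )
}

## region index containing each read midpoint (NA when outside all regions);
## midpoint of [start, end) is floor((start+end)/2), assigned left on a
## boundary because regions are half-open
.assignReads <- function(reads, regions) {
  mid <- floor((reads$start + reads$end) / 2)
  gr <- GenomicRanges::GRanges(
    reads$chrom,
    IRanges::IRanges(start = mid + 1L, width = 1L)
  )
  # reads on chromosomes absent from the regions simply find no overlap
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, regions, select = "first")
  )
  as.integer(hits)
}

#' Bin reads of one sample into a read-average count tensor
#'
#' Each read with at least \code{minCpgs} CpG sites whose midpoint falls in a
#' region contributes one count to that region's bin given by its discretised
#' read average. Reads outside all regions, or with too few CpGs, are dropped
#' and tallied in the result's \code{metadata}.
#'
#' @param reads Read data.frame (chrom, start, end, states; 0-based
#'   half-open).
#' @param regions \code{GRanges} of disjoint regions (e.g. from
#'   \code{\link{parseRegionsBed}} or \code{\link{makeWindows}}).
#' @param minCpgs Minimum CpGs per read (default 3).
#' @param individualId Sample name for the single row of the tensor.
#' @return A \code{ReadCountTensor} with one individual;
#'   \code{metadata(x)$retained} and \code{$dropped*} give the tallies, and
#'   \code{metadata(x)$retainedPerRegion} the per-region retained counts.
#' @export
binReads <- function(reads, regions, minCpgs = 3L, individualId = "sample") {
  .validateReads(reads)
  regions <- .validateRegions(regions)
  nM <- length(regions)
  avg <- vapply(
    strsplit(as.character(reads$states), ""),
    function(s) {
      s <- as.integer(s)
      if (anyNA(s) || !all(s %in% c(0L, 1L))) stop("states must be over {0,1}")
      if (length(s) < minCpgs) NA_real_ else mean(s)
    },
    numeric(1)
  )
  keepCpg <- !is.na(avg)
  region <- rep(NA_integer_, nrow(reads))
  if (any(keepCpg)) {
    region[keepCpg] <- .assignReads(reads[keepCpg, , drop = FALSE], regions)
  }
  keep <- keepCpg & !is.na(region)
  cts <- array(0, c(1L, nM, 5L))
  if (any(keep)) {
    bins <- encodeRead(avg[keep])
    tab <- tabulate(region[keep] + nM * (bins - 1L), nbins = nM * 5L)
    cts[1L, , ] <- tab
  }
  out <- ReadCountTensor(cts,
    regionIds = .regionLabels(regions),
    individualIds = individualId
  )
  out@metadata <- list(
    retained = sum(keep),
    droppedFewCpgs = sum(!keepCpg),
    droppedOutsideRegions = sum(keepCpg & is.na(region)),
    retainedPerRegion = tabulate(region[keep], nbins = nM)
  )
  out
}

#' Aggregate per-cell-type reads into a reference tensor
#'
#' Applies \code{\link{binReads}} to each cell type's reads and stacks the
#' results on the cell-type axis.
#'
#' @param readsByCellType Named list of read data.frames, one per cell type.
#' @param regions \code{GRanges} of disjoint regions.
#' @param minCpgs Minimum CpGs per read (default 3).
#' @return A \code{ReferenceTensor}.
#' @export
aggregateReference <- function(readsByCellType, regions, minCpgs = 3L) {
  stopifnot(is.list(readsByCellType), length(readsByCellType) >= 1)
  nms <- names(readsByCellType)
  if (is.null(nms)) nms <- paste0("celltype_", seq_along(readsByCellType))
  regions <- .validateRegions(regions)
  nM <- length(regions)
  cts <- array(0, c(length(readsByCellType), nM, 5L))
  for (t in seq_along(readsByCellType)) {
    cts[t, , ] <- counts(binReads(readsByCellType[[t]], regions,
      minCpgs = minCpgs
    ))[1L, , ]
  }
  ReferenceTensor(cts, cellTypeIds = nms, regionIds = .regionLabels(regions))
}
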
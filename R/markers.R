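## Discovery of cell-type-informative marker regions: tile the genome into
## 500 bp windows, summarise each cell type's methylation per window, and keep
## windows where one cell type is hypomethylated below the minimum of all
## others, subject to depth and exclusivity filters.

#' Tile chromosomes into fixed-size windows
#'
#' @param chromLengths Named integer vector of chromosome lengths (bp).
#' @param windowSize Window width in bp (default 500); the last window of a
#'   chromosome is truncated.
#' @return \code{GRanges} of non-overlapping tiling windows.
#' @export
#' @examples
#' makeWindows(c(chr1 = 1200))
makeWindows <- function(chromLengths, windowSize = 500L) {
  stopifnot(!is.null(names(chromLengths)), all(chromLengths > 0))
  parts <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(0L, len - 1L, by = windowSize)
    data.frame(chrom = ch, start = starts + 1L,
      end = pmin(starts + windowSize, len))
  })
  df <- do.call(rbind, parts)
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start, end = df$end)
  )
}

#' Summarise methylation per window and cell type
#'
#' In \code{"read_average"} mode each retained read (>= \code{minCpgs} CpGs)
#' contributes its read average once to the window holding its midpoint; the
#' summary value is the mean of read averages and the depth is the number of
#' contributing reads. In \code{"count"} mode all CpG measurements of a read
#' are pooled into its window; the summary value is methylated/total CpG
#' counts and the depth is the total CpG count.
#'
#' @param readsByCellType Named list of read data.frames.
#' @param regions \code{GRanges} windows (e.g. \code{\link{makeWindows}}).
#' @param mode \code{"read_average"} or \code{"count"}.
#' @param minCpgs Minimum CpGs per read in read-average mode (default 3).
#' @param excludeRegions Optional \code{GRanges} mask (e.g. SNPs, sex
#'   chromosomes): reads whose midpoint falls inside it are discarded before
#'   summarisation.
#' @return \code{data.frame} with one row per window: \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), then \code{mean.<ct>} and
#'   \code{depth.<ct>} per cell type. Windows with no reads in a cell type
#'   have depth 0 and \code{NA} mean.
#' @export
summarizeWindows <- function(readsByCellType, regions,
                             mode = c("read_average", "count"),
                             minCpgs = 3L, excludeRegions = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(readsByCellType), length(readsByCellType) >= 1)
  nms <- names(readsByCellType)
  if (is.null(nms)) nms <- paste0("celltype_", seq_along(readsByCellType))
  regions <- .validateRegions(regions)
  nM <- length(regions)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = BiocGenerics::start(regions) - 1L,
    end = BiocGenerics::end(regions),
    stringsAsFactors = FALSE
  )
  for (t in seq_along(readsByCellType)) {
    reads <- .validateReads(readsByCellType[[t]])
    if (!is.null(excludeRegions) && nrow(reads) > 0) {
      masked <- !is.na(.assignReads(reads, BiocGenerics::sort(excludeRegions)))
      reads <- reads[!masked, , drop = FALSE]
    }
    stateList <- strsplit(as.character(reads$states), "")
    nCpg <- lengths(stateList)
    meth <- vapply(stateList, function(s) sum(s == "1"), numeric(1))
    if (mode == "read_average") {
      keep <- nCpg >= minCpgs
      value <- meth[keep] / nCpg[keep]
      weight <- rep(1, sum(keep))
    } else {
      keep <- rep(TRUE, nrow(reads))
      value <- ifelse(nCpg > 0, meth / nCpg, 0)
      weight <- nCpg
    }
    region <- rep(NA_integer_, length(value))
    if (any(keep)) {
      region <- .assignReads(reads[keep, , drop = FALSE], regions)
    }
    ok <- !is.na(region)
    depth <- rep(0, nM)
    total <- rep(0, nM)
    if (any(ok)) {
      depth <- as.numeric(tapplySum(weight[ok], region[ok], nM))
      total <- as.numeric(tapplySum(value[ok] * weight[ok], region[ok], nM))
    }
    out[[paste0("mean.", nms[t])]] <- ifelse(depth > 0, total / depth, NA_real_)
    out[[paste0("depth.", nms[t])]] <- depth
  }
  out
}

## grouped sum over integer group ids 1..n
tapplySum <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Hypomethylation distance of one cell type in a window
#'
#' Distance of cell type \code{t} below all others:
#' \code{min(means[-t]) - means[t]}. Positive iff \code{t} is strictly the
#' least methylated cell type in the window.
#'
#' @param means Numeric vector of per-cell-type mean methylation in a window.
#' @param t Index of the candidate marker cell type.
#' @return Signed distance.
#' @export
#' @examples
#' markerDistance(c(0.1, 0.8, 0.9), 1)
markerDistance <- function(means, t) {
  stopifnot(length(means) >= 2, t >= 1, t <= length(means))
  min(means[-t]) - means[t]
}

## lower median: conservative, deterministic for even numbers of cell types
.lowerMedian <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Select marker regions
#'
#' Pipeline over window summaries: (1) eligibility -- every cell type has
#' depth >= 1, the (lower) median depth across cell types is at least
#' \code{depthThreshold}, and the candidate marker cell type itself reaches
#' \code{depthThreshold}; (2) per cell type, eligible windows where the cell
#' type is hypomethylated (positive \code{\link{markerDistance}}) are ranked
#' by decreasing distance, ties broken by genomic position; (3) any window in
#' the top \code{overlapK} of two or more cell types is removed from all; (4)
#' the top \code{topK} surviving windows per cell type are returned.
#'
#' @param summaries Window summary data.frame from
#'   \code{\link{summarizeWindows}}.
#' @param mode \code{"read_average"} (default depth threshold 20) or
#'   \code{"count"} (default 150).
#' @param depthThreshold Minimum per-window depth; defaults per mode.
#' @param topK Markers retained per cell type (default 100).
#' @param overlapK Depth of the cross-cell-type exclusivity comparison
#'   (default 150).
#' @param requireHypomethylated Keep only positive distances (default
#'   \code{TRUE}; disabling is for exploratory use only).
#' @return \code{data.frame} of markers: \code{chrom}, \code{start},
#'   \code{end}, \code{cellType}, \code{distance}, \code{rank},
#'   \code{ownDepth}, \code{medianDepth}. Emits a warning when a cell type has
#'   fewer than \code{topK} surviving windows.
#' @export
selectMarkers <- function(summaries, mode = c("read_average", "count"),
                          depthThreshold = NULL, topK = 100L,
                          overlapK = 150L, requireHypomethylated = TRUE) {
  mode <- match.arg(mode)
  if (is.null(depthThreshold)) {
    depthThreshold <- if (mode == "read_average") 20 else 150
  }
  meanCols <- grep("^mean\\.", names(summaries), value = TRUE)
  cellNames <- sub("^mean\\.", "", meanCols)
  nT <- length(cellNames)
  stopifnot(nT >= 2)
  means <- as.matrix(summaries[, paste0("mean.", cellNames)])
  depths <- as.matrix(summaries[, paste0("depth.", cellNames)])
  medianDepth <- apply(depths, 1, .lowerMedian)
  allCovered <- rowSums(depths >= 1) == nT

  ranked <- vector("list", nT)
  for (t in seq_len(nT)) {
    eligible <- allCovered & medianDepth >= depthThreshold &
      depths[, t] >= depthThreshold
    dist <- apply(means, 1, function(v) {
      if (anyNA(v)) NA_real_ else markerDistance(v, t)
    })
    cand <- which(eligible & !is.na(dist) &
      (if (requireHypomethylated) dist > 0 else TRUE))
    if (length(cand) == 0) {
      ranked[[t]] <- integer(0)
      next
    }
    ord <- cand[order(-dist[cand], summaries$chrom[cand],
      summaries$start[cand])]
    ranked[[t]] <- ord
  }

  ## exclusivity: windows in the top overlapK of >= 2 cell types are dropped
  topLists <- lapply(ranked, function(r) utils::head(r, overlapK))
  shared <- unlist(topLists)
  shared <- unique(shared[duplicated(shared)])

  out <- list()
  for (t in seq_len(nT)) {
    surv <- setdiff(ranked[[t]], shared)
    surv <- utils::head(surv, topK)
    if (length(surv) < topK) {
      warning(sprintf(
        "cell type %s: only %d of %d requested markers survive the filters",
        cellNames[t], length(surv), topK
      ))
    }
    if (length(surv) == 0) next
    dist <- vapply(surv, function(w) markerDistance(means[w, ], t), numeric(1))
    out[[t]] <- data.frame(
      chrom = summaries$chrom[surv],
      start = summaries$start[surv],
      end = summaries$end[surv],
      cellType = cellNames[t],
      distance = dist,
      rank = seq_along(surv),
      ownDepth = depths[surv, t],
      medianDepth = medianDepth[surv],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      cellType = character(0), distance = numeric(0), rank = integer(0),
      ownDepth = numeric(0), medianDepth = numeric(0)
    )
  }
  rownames(res) <- NULL
  res
}

#' Write markers as BED4
#'
#' @param markers Marker data.frame from \code{\link{selectMarkers}}.
#' @param path Output BED file (chrom, start, end, marker cell type).
#' @return The path, invisibly.
#' @export
writeMarkersBed <- function(markers, path) {
  utils::write.table(
    markers[, c("chrom", "start", "end", "cellType")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
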
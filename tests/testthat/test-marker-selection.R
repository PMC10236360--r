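test_that("makeWindows tiles chromosomes with a truncated last window", {
  w <- makeWindows(c(chr1 = 1200))
  expect_equal(BiocGenerics::start(w) - 1L, c(0L, 500L, 1000L))
  expect_equal(BiocGenerics::end(w), c(500L, 1000L, 1200L))
})

test_that("summarizeWindows averages read averages per cell type", {
  win <- oneWindow()
  # read averages 0 and 0.5
  reads <- makeReads(c("000", "1100"))
  s <- summarizeWindows(list(ct1 = reads), win)
  expect_equal(s$mean.ct1, 0.25)
  expect_equal(s$depth.ct1, 2)

  # empty window: depth 0, undefined mean
  wins <- makeWindows(c(chr1 = 1000))
  s2 <- summarizeWindows(list(ct1 = reads), wins)
  expect_equal(s2$depth.ct1, c(2, 0))
  expect_true(is.na(s2$mean.ct1[2]))

  # count mode pools CpG measurements, weighting reads by their CpG number
  s3 <- summarizeWindows(list(ct1 = reads), win, mode = "count")
  expect_equal(s3$depth.ct1, 7) # 3 + 4 CpG measurements
  expect_equal(s3$mean.ct1, 2 / 7)
})

test_that("an exclusion mask removes reads before summarisation", {
  win <- oneWindow()
  reads <- data.frame(
    chrom = "chr1", start = c(0L, 150L, 300L), end = c(100L, 250L, 400L),
    states = c("000", "1100", "111"), stringsAsFactors = FALSE
  ) # midpoints 50, 200, 350
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 301, end = 500))
  s <- summarizeWindows(list(ct1 = reads), win, excludeRegions = mask)
  expect_equal(s$depth.ct1, 2) # third read masked out
  expect_equal(s$mean.ct1, 0.25)
})

test_that("markerDistance is the margin below the closest other cell type", {
  expect_equal(markerDistance(c(0.1, 0.8, 0.9), 1), 0.7)
  expect_equal(markerDistance(c(0.8, 0.1, 0.9), 1), -0.7)
  expect_equal(markerDistance(c(0.5, 0.5, 0.5), 2), 0)
})

test_that("selectMarkers applies depth, hypomethylation and exclusivity filters", {
  ct <- c("ct1", "ct2", "ct3")
  hypo <- rep(1:3, length.out = 900)
  s <- makeSummaries(900, ct, hypo, depth = 100)

  mk <- selectMarkers(s, depthThreshold = 20, topK = 100, overlapK = 150)
  # plenty of eligible windows: exactly topK per cell type
  expect_equal(nrow(mk), 300)
  expect_equal(unname(table(mk$cellType)), rep(100L, 3), ignore_attr = TRUE)
  # markers are pairwise-distinct windows
  expect_false(any(duplicated(mk[, c("chrom", "start")])))
  # every marker satisfies the advertised filters
  expect_true(all(mk$distance > 0))
  expect_true(all(mk$ownDepth >= 20))
  expect_true(all(mk$medianDepth >= 20))

  # the marker cell type's own depth must reach the threshold
  s2 <- s
  s2$depth.ct1[hypo == 1] <- 5 # median of (5, 100, 100) still passes
  expect_warning(
    mk2 <- selectMarkers(s2, depthThreshold = 20, topK = 100),
    "survive"
  )
  expect_false("ct1" %in% mk2$cellType)

  # a cell type with zero depth makes the window ineligible for everyone
  s3 <- s
  s3$depth.ct2 <- 0
  mk3 <- suppressWarnings(selectMarkers(s3, depthThreshold = 20, topK = 100))
  expect_equal(nrow(mk3), 0)

  # selection is invariant to cell-type column order
  sPerm <- s[, c(
    "chrom", "start", "end",
    "mean.ct3", "depth.ct3", "mean.ct1", "depth.ct1",
    "mean.ct2", "depth.ct2"
  )]
  mkPerm <- selectMarkers(sPerm, depthThreshold = 20, topK = 100)
  key <- function(m) {
    o <- order(m$cellType, m$chrom, m$start)
    m[o, c("chrom", "start", "cellType", "distance")]
  }
  expect_equal(key(mkPerm), key(mk), ignore_attr = TRUE)
})

test_that("windows ranked highly by several cell types are excluded from all", {
  # with the hypomethylation filter off, a flat window ranks for many types
  ct <- c("ct1", "ct2")
  s <- makeSummaries(10, ct, hypo = rep(0, 10), depth = 100)
  # make window 1 the top-ranked window of BOTH cell types
  s$mean.ct1 <- c(0.10, seq(0.5, 0.9, length.out = 9))
  s$mean.ct2 <- c(0.12, seq(0.9, 0.5, length.out = 9))
  mk <- suppressWarnings(selectMarkers(s,
    depthThreshold = 20, topK = 3,
    overlapK = 5, requireHypomethylated = FALSE
  ))
  expect_false(any(mk$start == 0)) # window 1 removed from both cell types
  # with the default hypomethylation filter each window has at most one
  # positive-distance cell type, so nothing overlaps
  mkDef <- suppressWarnings(selectMarkers(s, depthThreshold = 20, topK = 3))
  expect_true(all(mkDef$distance > 0))
})

test_that("marker pipeline runs end to end on simulated reads", {
  set.seed(12)
  wins <- makeWindows(c(chr1 = 20000))
  nW <- length(wins)
  ct <- c("alpha", "beta")
  # each cell type hypomethylated in its own block of windows
  thetaA <- rep(0.8, nW); thetaA[1:15] <- 0.05
  thetaB <- rep(0.8, nW); thetaB[26:40] <- 0.05
  reads <- list(
    alpha = simulateReads(thetaA, wins, meanDepth = 40, seed = 1),
    beta = simulateReads(thetaB, wins, meanDepth = 40, seed = 2)
  )
  s <- summarizeWindows(reads, wins)
  mk <- suppressWarnings(selectMarkers(s, depthThreshold = 20, topK = 15))
  expect_true(all(mk$distance > 0))
  hits <- mk[mk$cellType == "alpha", "start"] / 500 + 1
  expect_true(all(hits %in% 1:15))

  bed <- tempfile(fileext = ".bed")
  writeMarkersBed(mk, bed)
  gr <- parseRegionsBed(bed)
  expect_equal(length(gr), nrow(mk))
})
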
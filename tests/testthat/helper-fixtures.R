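# Shared fixture builders; everything is generated in code.

# tiny deterministic input/reference pair with valid shapes
tinyTensors <- function(nN = 2, nT = 3, nM = 4, seed = 42, depth = 12) {
  set.seed(seed)
  x <- array(rpois(nN * nM * 5, depth / 5), c(nN, nM, 5))
  y <- array(rpois(nT * nM * 5, depth / 5), c(nT, nM, 5))
  list(x = ReadCountTensor(x), y = ReferenceTensor(y))
}

# reads covering one 500 bp window starting at `offset`
makeReads <- function(states, chrom = "chr1", offset = 0L) {
  n <- length(states)
  data.frame(
    chrom = rep(chrom, n),
    start = offset + seq(10L, by = 5L, length.out = n),
    end = offset + seq(10L, by = 5L, length.out = n) + 100L,
    states = states,
    stringsAsFactors = FALSE
  )
}

oneWindow <- function(chrom = "chr1", start0 = 0L, width = 500L) {
  GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = start0 + 1L, width = width)
  )
}

# nearest-bin-center oracle with round-half-up tie break, written
# independently of encodeRead
nearestBinOracle <- function(avg) {
  centers <- c(0, 0.25, 0.5, 0.75, 1)
  d <- abs(avg - centers)
  which(d == min(d))[sum(d == min(d))] # ties -> highest center
}

# synthetic window summaries for marker selection: `hypo` gives, per window,
# the cell type made clearly hypomethylated (0 = none)
makeSummaries <- function(nWindows, cellTypes, hypo, depth = 100,
                          lowMean = 0.1, highMean = 0.8, seed = 1) {
  set.seed(seed)
  out <- data.frame(
    chrom = "chr1",
    start = (seq_len(nWindows) - 1L) * 500L,
    end = seq_len(nWindows) * 500L
  )
  for (t in seq_along(cellTypes)) {
    m <- rep(highMean, nWindows) + runif(nWindows, 0, 0.15)
    m[hypo == t] <- lowMean + runif(sum(hypo == t), 0, 0.05)
    out[[paste0("mean.", cellTypes[t])]] <- pmin(m, 1)
    out[[paste0("depth.", cellTypes[t])]] <- rep(depth, nWindows)
  }
  out
}
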
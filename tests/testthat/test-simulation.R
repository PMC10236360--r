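test_that("generated data respects the model's sampling assumptions", {
  sim <- simulateGeneratedData(
    nCellTypes = 4, nRegions = 30,
    nIndividuals = 3, depthMean = 8, seed = 2
  )
  expect_s4_class(sim$x, "ReadCountTensor")
  expect_s4_class(sim$y, "ReferenceTensor")
  expect_equal(rowSums(sim$alphaTrue), rep(1, 3), tolerance = 1e-12)
  expect_equal(apply(sim$betaTrue, c(1, 2), sum), matrix(1, 4, 30),
    tolerance = 1e-12
  )

  # bit-reproducible under the same seed
  again <- simulateGeneratedData(
    nCellTypes = 4, nRegions = 30,
    nIndividuals = 3, depthMean = 8, seed = 2
  )
  expect_identical(counts(sim$x), counts(again$x))

  # zero depth -> all-zero tensors
  empty <- simulateGeneratedData(
    nCellTypes = 2, nRegions = 5,
    nIndividuals = 1, depthMean = 0, seed = 1
  )
  expect_true(all(counts(empty$x) == 0) && all(counts(empty$y) == 0))

  # empirical bin frequencies at a fixed (t, m) match the true distribution:
  # a single cell type and region at large depth is pure multinomial sampling
  big <- simulateGeneratedData(
    nCellTypes = 1, nRegions = 1,
    nIndividuals = 1, depthMean = 1e5, seed = 3
  )
  n <- sum(counts(big$x))
  freq <- counts(big$x)[1, 1, ] / n
  se <- sqrt(big$betaTrue[1, 1, ] * (1 - big$betaTrue[1, 1, ]) / n)
  expect_true(all(abs(freq - big$betaTrue[1, 1, ]) <= 3 * se + 1e-12))
})

test_that("CpG-count data follows the binomial assumptions", {
  sim <- simulateCelfieData(
    nCellTypes = 3, nRegions = 40, nIndividuals = 2,
    depthMean = 9, seed = 4
  )
  cc <- sim$counts
  expect_true(all(cc@xMeth <= cc@xDepth) && all(cc@yMeth <= cc@yDepth))
  expect_true(all(sim$betaTrue >= 0 & sim$betaTrue <= 1))

  # extreme methylation fractions force the read outcomes
  one <- celfeer:::.generateCelfieFromTruth(
    matrix(c(0.5, 0.5), 1), matrix(1, 2, 50), 20
  )
  expect_equal(one@xMeth, one@xDepth)
  zero <- celfeer:::.generateCelfieFromTruth(
    matrix(c(0.5, 0.5), 1), matrix(0, 2, 50), 20
  )
  expect_true(all(zero@xMeth == 0))

  # law of large numbers: methylated fraction approaches the truth
  set.seed(6)
  beta <- matrix(0.3, 1, 1)
  big <- celfeer:::.generateCelfieFromTruth(matrix(1), beta, 2e5)
  phat <- big@xMeth[1, 1] / big@xDepth[1, 1]
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / big@xDepth[1, 1]))
})

test_that("two-group rare design puts the rare type only in group A", {
  sim <- simulateTwoGroupRare(seed = 5)
  expect_equal(dim(sim$alphaTrue), c(10, 10))
  expect_equal(rowSums(sim$alphaTrue), rep(1, 10), tolerance = 1e-12)
  expect_true(all(sim$alphaTrue[sim$group == "B", sim$rareIndex] == 0))
  expect_true(all(sim$alphaTrue[sim$group == "A", sim$rareIndex] > 0))

  # normalisation arithmetic: recompute the draws independently
  set.seed(5)
  for (n in 1:10) {
    bg <- runif(9, 0.5, 1)
    rare <- if (n <= 5) 0.01 else 0
    expect_equal(sim$alphaTrue[n, ], c(rare, bg) / sum(c(rare, bg)),
      tolerance = 1e-12
    )
  }

  # the celfie variant draws identical truths under the same seed
  simC <- simulateTwoGroupRare(model = "celfie", seed = 5)
  expect_identical(sim$alphaTrue, simC$alphaTrue)
  expect_s4_class(simC$counts, "CpGCounts")
})

test_that("unknown experiment masks the last cell type and clips its truth", {
  sim <- simulateUnknownExperiment(seed = 6)
  expect_true(all(counts(sim$y)[sim$unknownIndex, , ] == 0))
  expect_true(unknownMask(sim$y)[sim$unknownIndex])
  expect_true(all(sim$unknownTrue >= 0 & sim$unknownTrue <= 1))
  expect_equal(sim$alphaTrue[, sim$unknownIndex], sim$unknownTrue)
  expect_equal(rowSums(sim$alphaTrue), rep(1, 10), tolerance = 1e-12)

  simC <- simulateUnknownExperiment(model = "celfie", seed = 6)
  expect_true(all(simC$counts@yDepth[simC$unknownIndex, ] == 0))

  # moments of the unknown truth match the clipped normal (cheap design:
  # many individuals, no reads)
  big <- simulateUnknownExperiment(
    nRegions = 1, nIndividuals = 10000,
    depthMean = 0, seed = 7
  )
  clippedMean <- stats::integrate(
    function(z) pmin(pmax(z, 0), 1) * dnorm(z, 0.2, 0.1), -2, 2
  )$value
  se <- sd(big$unknownTrue) / sqrt(10000)
  expect_lt(abs(mean(big$unknownTrue) - clippedMean), 4 * se)
})

test_that("mixReads normalises cell types and honours proportions", {
  set.seed(8)
  wins <- makeWindows(c(chr1 = 5000))
  readsByCt <- list(
    a = simulateReads(runif(10), wins, meanDepth = 30, seed = 1),
    b = simulateReads(runif(10), wins, meanDepth = 60, seed = 2)
  )
  # a single non-zero proportion returns only that cell type's reads
  onlyA <- suppressWarnings(mixReads(readsByCt, c(1, 0), seed = 3))
  expect_true(all(onlyA$states %in% readsByCt$a$states))

  # total read count tracks coverageFactor * nRegions
  mix <- mixReads(readsByCt, c(0.5, 0.5),
    coverageFactor = 20,
    nRegions = 10, seed = 4
  )
  expect_lt(abs(nrow(mix) - 200), 3 * sqrt(200))

  expect_error(mixReads(readsByCt, c(0, 0)), "all zero")
  expect_error(mixReads(readsByCt, c(-1, 2)), "non-negative")

  # count-tensor analogue preserves the expected total
  cts <- list(
    matrix(rpois(50, 10), 10, 5),
    matrix(rpois(50, 10), 10, 5)
  )
  mixedCounts <- mixCounts(cts, c(0.3, 0.7), coverageFactor = 20, seed = 5)
  expect_s4_class(mixedCounts, "ReadCountTensor")
  expect_lt(abs(sum(counts(mixedCounts)) - 200), 3 * sqrt(200))
})

test_that("injectNoise flips states at the requested rate", {
  set.seed(9)
  wins <- makeWindows(c(chr1 = 5000))
  reads <- simulateReads(runif(10), wins, meanDepth = 100, cpgsPerRead = 20, seed = 1)

  expect_identical(injectNoise(reads, 0), reads)

  inverted <- injectNoise(reads, 1)
  flip <- function(s) {
    paste(
      ifelse(strsplit(s, "")[[1]] == "1", "0", "1"),
      collapse = ""
    )
  }
  expect_equal(inverted$states, vapply(reads$states, flip, character(1)),
    ignore_attr = TRUE
  )
  expect_equal(nchar(inverted$states), nchar(reads$states))

  p <- 0.05
  noisy <- injectNoise(reads, p, seed = 2)
  nStates <- sum(nchar(reads$states))
  flipped <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$states, noisy$states)
  rate <- sum(flipped) / nStates
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / nStates))

  expect_error(injectNoise(reads, 1.5), "\\[0, 1\\]")

  # count-mode analogue: flip rate matches in expectation, depths unchanged
  set.seed(10)
  depth <- matrix(2000L, 5, 5)
  meth <- matrix(1000L, 5, 5)
  noisy <- injectNoiseCounts(meth, depth, 1)
  expect_equal(noisy, depth - meth)
  noisy2 <- injectNoiseCounts(meth, depth, 0.1, seed = 3)
  expect_true(all(noisy2 <= depth))
  expect_lt(abs(mean(noisy2) - 1000), 3 * sqrt(2000 * 0.1 * 0.9 / 5))
})
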
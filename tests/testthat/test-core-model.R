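test_that("initializeParameters normalises reference counts into bin distributions", {
  y <- array(0, c(2, 2, 5))
  y[1, 1, ] <- c(4, 0, 0, 0, 4)
  y[1, 2, ] <- c(10, 0, 0, 0, 0)
  # cell type 2 left all-zero: an unknown cell type
  init <- initializeParameters(y, nIndividuals = 3, seed = 7)

  expect_equal(init$beta[1, 1, ], c(0.5, 0, 0, 0, 0.5), tolerance = 1e-8)
  expect_equal(init$beta[1, 2, ], c(1, 0, 0, 0, 0), tolerance = 1e-8)
  # unknown cell type starts from the uniform bin distribution everywhere
  expect_equal(init$beta[2, 1, ], rep(0.2, 5), tolerance = 1e-9)
  expect_equal(init$beta[2, 2, ], rep(0.2, 5), tolerance = 1e-9)
  # alpha rows are proportions
  expect_equal(rowSums(init$alpha), rep(1, 3), tolerance = 1e-12)
  expect_true(all(init$alpha > 0 & init$alpha < 1))
  # every beta entry is floored strictly above zero
  expect_true(all(init$beta > 0))

  again <- initializeParameters(y, nIndividuals = 3, seed = 7)
  expect_identical(init, again)
  other <- initializeParameters(y, nIndividuals = 3, seed = 8)
  expect_false(identical(init$alpha, other$alpha))

  expect_error(initializeParameters(array(-1, c(1, 1, 5)), 1), "non-negative")
})

test_that("eStep computes the read-origin posterior", {
  # single component: posterior is 1 everywhere
  x1 <- array(1, c(2, 3, 5))
  b1 <- array(0.2, c(1, 3, 5))
  p1 <- eStep(x1, matrix(1, 2, 1), b1)
  expect_true(all(p1 == 1))

  # two components, hand arithmetic at bin 1
  alpha <- matrix(c(0.6, 0.4), 1)
  beta <- array(0.2, c(2, 1, 5))
  beta[1, 1, ] <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  beta[2, 1, ] <- c(0.1, 0.3, 0.2, 0.2, 0.2)
  p <- eStep(array(1, c(1, 1, 5)), alpha, beta)
  expect_equal(p[1, 1, 1, 1], 0.3 / 0.34, tolerance = 1e-12)
  expect_equal(p[1, 2, 1, 1], 0.04 / 0.34, tolerance = 1e-12)
  # posterior sums to one over cell types at every (n, m, i)
  expect_equal(apply(p, c(1, 3, 4), sum), array(1, c(1, 1, 5)),
    tolerance = 1e-12
  )

  # disjoint supports identify the origin exactly
  betaD <- array(0, c(2, 1, 5))
  betaD[1, 1, ] <- c(1, 0, 0, 0, 0)
  betaD[2, 1, ] <- c(0, 0, 0, 0, 1)
  pD <- eStep(array(1, c(1, 1, 5)), matrix(c(0.5, 0.5), 1), betaD)
  expect_equal(pD[1, , 1, 1], c(1, 0))
  expect_equal(pD[1, , 1, 5], c(0, 1))

  expect_error(eStep(array(1, c(1, 2, 5)), alpha, beta), "shape")
})

test_that("mStep recovers the closed-form updates", {
  # all posterior mass on cell type 1 -> alpha row (1, 0)
  x <- array(0, c(1, 2, 5))
  x[1, , 1] <- c(3, 2)
  y0 <- array(0, c(2, 2, 5))
  post <- array(0, c(1, 2, 2, 5))
  post[1, 1, , ] <- 1
  up <- mStep(x, y0, post)
  expect_equal(up$alpha[1, ], c(1, 0))

  # posterior 0.6/0.4 on 10 reads in one bin -> alpha (0.6, 0.4)
  x2 <- array(0, c(1, 1, 5))
  x2[1, 1, 1] <- 10
  post2 <- array(0, c(1, 2, 1, 5))
  post2[1, 1, 1, 1] <- 0.6
  post2[1, 2, 1, 1] <- 0.4
  up2 <- mStep(x2, array(0, c(2, 1, 5)), post2)
  expect_equal(up2$alpha[1, ], c(0.6, 0.4), tolerance = 1e-12)

  # no input reads: beta falls back to the reference proportions
  set.seed(1)
  y <- array(rpois(2 * 3 * 5, 6), c(2, 3, 5))
  x0 <- array(0, c(1, 3, 5))
  post0 <- array(0, c(1, 2, 3, 5))
  expect_warning(up0 <- mStep(x0, y, post0), "zero total reads")
  refProp <- y / rep(apply(y, c(1, 2), sum), 5)
  expect_equal(up0$beta, refProp, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(up0$alpha[1, ], c(0.5, 0.5))
})

test_that("expectedLogLikelihood matches a term-by-term summation oracle", {
  set.seed(3)
  nT <- 2; nM <- 1; nI <- 5
  x <- array(rpois(nM * nI, 3), c(1, nM, nI))
  y <- array(rpois(nT * nM * nI, 4), c(nT, nM, nI))
  init <- initializeParameters(y, 1, seed = 2)
  p <- eStep(x, init$alpha, init$beta)

  # independent oracle: explicit nested loops over the definition
  oracle <- 0
  for (t in seq_len(nT)) {
    for (m in seq_len(nM)) {
      for (i in seq_len(nI)) {
        coef <- p[1, t, m, i] * x[1, m, i] + y[t, m, i]
        if (coef > 0) oracle <- oracle + coef * log(init$beta[t, m, i])
        if (x[1, m, i] > 0 && init$alpha[1, t] > 0) {
          oracle <- oracle + p[1, t, m, i] * x[1, m, i] * log(init$alpha[1, t])
        }
      }
      oracle <- oracle + lgamma(sum(y[t, m, ]) + 1) -
        sum(lgamma(y[t, m, ] + 1))
    }
  }
  expect_equal(expectedLogLikelihood(x, y, init$alpha, init$beta, p), oracle,
    tolerance = 1e-10
  )

  # empty data: all sums are empty
  x0 <- array(0, c(1, 1, 5))
  y0 <- array(0, c(2, 1, 5))
  p0 <- array(0, c(1, 2, 1, 5))
  expect_equal(
    expectedLogLikelihood(
      x0, y0, matrix(c(0.5, 0.5), 1),
      array(0, c(2, 1, 5)), p0
    ), 0
  )
})

test_that("the EM objective is non-decreasing and matches the R step composition", {
  set.seed(10)
  for (k in 1:20) {
    nN <- sample(1:3, 1); nT <- sample(2:4, 1); nM <- sample(2:10, 1)
    x <- array(rpois(nN * nM * 5, 2), c(nN, nM, 5))
    y <- array(rpois(nT * nM * 5, 2), c(nT, nM, 5))
    if (sum(x) == 0) x[1, 1, 1] <- 3
    fit <- suppressWarnings(fitCelfeer(x, y,
      nRestarts = 1, seed = k,
      maxIter = 60, tol = 0, trackLikelihood = TRUE
    ))
    expect_true(all(diff(fit@llTrace) > -1e-8))
    # parameters respect the simplex constraints after every m step
    a <- cellTypeProportions(fit)
    b <- methylationProfiles(fit)
    expect_equal(rowSums(a), rep(1, nN), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(apply(b, c(1, 2), sum), matrix(1, nT, nM),
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }

  # one C++ iteration reproduces the R eStep/mStep composition
  set.seed(11)
  x <- array(rpois(2 * 4 * 5, 3), c(2, 4, 5))
  y <- array(rpois(3 * 4 * 5, 3), c(3, 4, 5))
  init <- initializeParameters(y, 2, seed = 5)
  fit1 <- suppressWarnings(fitCelfeer(x, y,
    nRestarts = 1, seed = 99, maxIter = 1, tol = 0,
    alphaInit = init$alpha, betaInit = init$beta
  ))
  p <- eStep(x, init$alpha, init$beta)
  up <- mStep(x, y, p)
  expect_equal(unname(cellTypeProportions(fit1)), up$alpha, tolerance = 1e-12)
  expect_equal(unname(methylationProfiles(fit1)), unname(up$beta),
    tolerance = 1e-12
  )
})

test_that("fit handles degenerate and symmetric inputs", {
  tt <- tinyTensors(nN = 2, nT = 1, nM = 4)
  y1 <- ReferenceTensor(array(counts(tt$y)[1, , ], c(1, 4, 5)))
  fit <- fitCelfeer(tt$x, y1, nRestarts = 2, seed = 1)
  expect_equal(unname(cellTypeProportions(fit)), matrix(1, 2, 1))

  # duplicated individual: identical proportion rows at convergence
  set.seed(20)
  x1 <- array(rpois(30 * 5, 4), c(1, 30, 5))
  x2 <- array(c(x1, x1), c(2, 30, 5))
  x2[1, , ] <- x1[1, , ]
  x2[2, , ] <- x1[1, , ]
  y <- array(rpois(3 * 30 * 5, 4), c(3, 30, 5))
  fit2 <- fitCelfeer(x2, y, nRestarts = 3, seed = 2, tol = 1e-7, maxIter = 20000)
  a <- cellTypeProportions(fit2)
  expect_equal(a[1, ], a[2, ], tolerance = 1e-3)

  expect_error(fitCelfeer(array(1, c(1, 0, 5)), array(1, c(2, 0, 5))),
    "at least one region"
  )
  # zero-read individual: uniform row and a warning
  x0 <- array(0, c(1, 4, 5))
  y3 <- counts(tinyTensors(nN = 1, nT = 3, nM = 4, seed = 77)$y)
  expect_warning(
    fit0 <- fitCelfeer(x0, y3, nRestarts = 1, seed = 1, maxIter = 5),
    "zero total reads"
  )
  expect_equal(unname(cellTypeProportions(fit0))[1, ], rep(1 / 3, 3))
})

test_that("with frozen beta the fit matches a grid-search oracle", {
  set.seed(30)
  for (k in 1:5) {
    nM <- sample(2:3, 1)
    beta <- array(0, c(2, nM, 5))
    for (m in seq_len(nM)) {
      beta[1, m, ] <- celfeer:::.rDirichlet(1, 5)
      beta[2, m, ] <- celfeer:::.rDirichlet(1, 5)
    }
    x <- array(rpois(nM * 5, 6), c(1, nM, 5))
    y0 <- array(0, c(2, nM, 5))
    fit <- fitCelfeer(x, y0,
      nRestarts = 3, seed = k, tol = 1e-9,
      maxIter = 20000, freezeBeta = TRUE, betaInit = beta
    )
    aHat <- cellTypeProportions(fit)[1, 1]

    # brute-force grid search over the marginal log-likelihood
    grid <- seq(0, 1, by = 0.001)
    ll <- vapply(grid, function(a) {
      mix <- a * beta[1, , ] + (1 - a) * beta[2, , ] # strictly positive
      sum(x[1, , ] * log(mix))
    }, numeric(1))
    aStar <- grid[which.max(ll)]
    expect_lt(abs(aHat - aStar), 2e-3)
  }
})

test_that("permuting reference cell types permutes the fitted proportions", {
  set.seed(40)
  x <- array(rpois(2 * 20 * 5, 5), c(2, 20, 5))
  y <- array(rpois(4 * 20 * 5, 5), c(4, 20, 5))
  init <- initializeParameters(y, 2, seed = 9)
  perm <- c(3, 1, 4, 2)
  fitA <- suppressWarnings(fitCelfeer(x, y,
    nRestarts = 1, seed = 1, maxIter = 200,
    alphaInit = init$alpha, betaInit = init$beta
  ))
  fitB <- suppressWarnings(fitCelfeer(x, y[perm, , ],
    nRestarts = 1, seed = 1, maxIter = 200,
    alphaInit = init$alpha[, perm], betaInit = init$beta[perm, , ]
  ))
  expect_equal(unname(cellTypeProportions(fitA))[, perm],
    unname(cellTypeProportions(fitB)),
    tolerance = 1e-10
  )
  expect_equal(logLik(fitA), logLik(fitB), tolerance = 1e-8)
})

test_that("maskUnknowns appends or zeroes flagged all-zero rows", {
  y <- ReferenceTensor(array(3, c(9, 4, 5)))
  expect_identical(maskUnknowns(y, 0), y)

  m1 <- maskUnknowns(y, 1)
  expect_equal(dim(counts(m1))[1], 10)
  expect_true(all(counts(m1)[10, , ] == 0))
  expect_equal(unname(unknownMask(m1)), c(rep(FALSE, 9), TRUE))
  expect_equal(cellTypes(m1)[10], "unknown_1")

  m2 <- maskUnknowns(y, 2)
  expect_equal(sum(unknownMask(m2)), 2)
  expect_true(all(counts(m2)[10:11, , ] == 0))

  z <- maskUnknowns(y, 1, append = FALSE)
  expect_equal(dim(counts(z))[1], 9)
  expect_true(all(counts(z)[9, , ] == 0))
  expect_true(unknownMask(z)[9])

  expect_error(maskUnknowns(y, -1), ">= 0")
})

test_that("containers enforce their invariants", {
  expect_error(ReadCountTensor(array(-1, c(1, 2, 5))), "non-negative")
  expect_error(ReadCountTensor(array(1, c(1, 2, 4))), "length 5")
  expect_error(
    ReferenceTensor(array(1, c(2, 2, 5)), unknownMask = c(TRUE, FALSE)),
    "all-zero"
  )
  expect_error(
    CpGCounts(
      xMeth = matrix(5, 1, 2), xDepth = matrix(4, 1, 2),
      yMeth = matrix(0, 2, 2), yDepth = matrix(1, 2, 2)
    ),
    "exceed"
  )
})

test_that("an unmasked reference recovers the masked-unknown design accurately", {
  # contrast for the masked-unknown benchmark: with the last cell type's
  # reference present, its proportions are recovered near the sampling limit,
  # so the large masked-design error is the cost of removing the reference,
  # not an optimiser defect
  sim <- simulateUnknownExperiment(seed = 51)
  yFull <- celfeer:::.generateReadReference(sim$betaTrue, 10)
  fit <- fitCelfeer(counts(sim$x), yFull, nRestarts = 4, seed = 52)
  est <- cellTypeProportions(fit)
  expect_gt(
    pearsonR(as.numeric(est), as.numeric(sim$alphaTrue)), 0.9
  )
  expect_lt(rmse(est[, sim$unknownIndex], sim$unknownTrue), 0.08)
})
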
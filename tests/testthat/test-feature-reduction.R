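test_that("data on a line load entirely on the first component", {
  withr::with_seed(1, t <- stats::rnorm(20))
  X <- outer(t, c(1, -2, 0.5, 3, 1))  # exact rank 1 in 5-D
  m <- pcaFit(X, k = 2)
  expect_equal(explainedVariance(m)[1], 1, tolerance = 1e-12)
  expect_equal(explainedVariance(m)[2], 0, tolerance = 1e-12)
})

test_that("full-rank reconstruction recovers the centred data", {
  withr::with_seed(2, X <- matrix(stats::rnorm(12 * 6), 12, 6))
  m <- pcaFit(X, k = 6)
  S <- pcaScores(m, X)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(S %*% t(m@loadings), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("explained variances match an independent eigen-decomposition", {
  withr::with_seed(3, X <- matrix(stats::rnorm(30 * 8), 30, 8))
  m <- pcaFit(X, k = 8)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(explainedVariance(m), ev / sum(ev), tolerance = 1e-10)
  ## training scores are column-centred with variances proportional to the
  ## explained fractions
  S <- pcaScores(m, X)
  expect_true(all(abs(colMeans(S)) < 1e-8))
  expect_equal(apply(S, 2, stats::var) / sum(ev), explainedVariance(m),
               tolerance = 1e-10)
  ## sign convention: dominant entry of each loading is positive
  for (j in seq_len(ncol(m@loadings))) {
    expect_gt(m@loadings[which.max(abs(m@loadings[, j])), j], 0)
  }
  expect_error(pcaFit(X, k = 30), "must not exceed")
})

test_that("Mahalanobis distance matches hand-computed values", {
  expect_equal(mahalanobisSq(c(1, 2, 3), c(0, 0, 0), diag(c(1, 4, 9))), 3)
  expect_equal(mahalanobisSq(c(2, 5), c(2, 5), diag(2)), 0)
  ## identity covariance reduces to squared Euclidean distance
  withr::with_seed(4, {
    x <- stats::rnorm(6)
    m <- stats::rnorm(6)
  })
  expect_equal(mahalanobisSq(x, m, diag(6)), sum((x - m)^2))
  expect_error(mahalanobisSq(c(1, 2), c(0, 0, 0), diag(3)), "mismatch")
})

test_that("G is the mean own-over-wrong squared-distance ratio", {
  ## training: class means 0 and 4, unit pooled variance
  Xtr <- matrix(c(-1, 0, 1, 3, 4, 5), ncol = 1)
  ytr <- c("NILM", "NILM", "NILM", "SIL", "SIL", "SIL")
  ## validation points 1 (NILM) and 3 (SIL): g = 1/9 each
  G <- fitnessG(1, Xtr, ytr, matrix(c(1, 3), ncol = 1), c("NILM", "SIL"))
  expect_equal(G, 1 / 9)
  ## a validation sample exactly at its class mean contributes 0
  expect_equal(fitnessG(1, Xtr, ytr, matrix(0), "NILM"), 0)
  ## equidistant sample contributes exactly 1
  expect_equal(fitnessG(1, Xtr, ytr, matrix(2), "SIL"), 1)
})

test_that("fitnessG and the GA fast path match the explicit-loop oracle", {
  for (seed in 1:25) {
    d <- makePlantedCohort(seed, nPerClass = 20, p = 12, shift = 1)
    withr::with_seed(seed * 31, {
      sel <- sort(sample(12, sample(2:6, 1)))
    })
    expected <- bruteFitnessG(sel, d$X[d$train, ], d$labels[d$train],
                              d$X[d$validation, ], d$labels[d$validation])
    expect_equal(fitnessG(sel, d$X[d$train, ], d$labels[d$train],
                          d$X[d$validation, ], d$labels[d$validation]),
                 expected, tolerance = 1e-10)
    expect_equal(lipoclass:::.fastFitnessG(
                   sel, d$X[d$train, ], d$labels[d$train],
                   d$X[d$validation, ], d$labels[d$validation]),
                 expected, tolerance = 1e-10)
  }
})

test_that("a degenerate GA (no crossover, no mutation) returns its best initial chromosome", {
  d <- makePlantedCohort(7, nPerClass = 30, p = 15)
  cfg <- gaConfig(nGenerations = 5, population = 20, crossoverProb = 0,
                  mutationProb = 0, nRestarts = 1, seed = 99)
  res <- gaSelect(d$X[d$train, ], d$labels[d$train],
                  d$X[d$validation, ], d$labels[d$validation], cfg)
  ## rebuild the same initial population and evaluate it directly
  best <- withr::with_seed(99, {
    P <- matrix(stats::runif(20 * 15) < cfg@initBitProb, nrow = 20)
    for (i in 1:20) if (!any(P[i, ])) P[i, sample.int(15, 1)] <- TRUE
    fits <- apply(P, 1, function(b) {
      fitnessG(which(b), d$X[d$train, ], d$labels[d$train],
               d$X[d$validation, ], d$labels[d$validation])
    })
    list(fit = min(fits), sel = sort(which(P[which.min(fits), ])))
  })
  expect_equal(res@bestFitness, best$fit)
  expect_identical(selectedVariables(res), as.integer(best$sel))
})

test_that("the best-so-far fitness is non-increasing within each restart", {
  d <- makePlantedCohort(3, nPerClass = 30, p = 20)
  res <- gaSelect(d$X[d$train, ], d$labels[d$train],
                  d$X[d$validation, ], d$labels[d$validation],
                  gaConfig(nGenerations = 10, population = 20,
                           nRestarts = 2, seed = 5))
  expect_length(res@fitnessHistory, 2)
  for (h in res@fitnessHistory) {
    expect_length(h, 10)
    expect_true(all(diff(h) <= 0))
  }
})

test_that("the GA respects the variable cap and recovers planted variables", {
  d <- makePlantedCohort(1)
  cfg <- gaConfig(seed = 1)
  res <- gaSelect(d$X[d$train, ], d$labels[d$train],
                  d$X[d$validation, ], d$labels[d$validation], cfg)
  expect_lte(length(selectedVariables(res)), cfg@maxVariables)
  expect_true(all(d$planted %in% selectedVariables(res)))
  expect_gte(res@bestFitness, 0)
})

test_that("GA configuration invariants are enforced", {
  expect_error(gaConfig(population = 1), "population")
  expect_error(gaConfig(population = 81), "even")
  expect_error(gaConfig(crossoverProb = 1.2), "crossoverProb")
})
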
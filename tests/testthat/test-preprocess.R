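test_that("identical axes stack without merging", {
  mz <- c(300.1, 450.2, 800.3)
  a <- massSpectrum("a", "NILM", mz, c(1, 2, 3))
  b <- massSpectrum("b", "SIL", mz, c(4, 5, 6))
  fm <- buildCommonAxis(list(a, b))
  expect_equal(mzAxis(fm), mz)
  expect_equal(unname(intensityMatrix(fm)),
               rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_false(isNormalized(fm))
  expect_false(isRoiCompressed(fm))
})

test_that("merging honours the ppm tolerance (2.5 ppm gap at m/z 400)", {
  a <- massSpectrum("a", "NILM", 400.0000, 10)
  b <- massSpectrum("b", "SIL", 400.0010, 30)
  merged <- buildCommonAxis(list(a, b), mergeTolPpm = 5)
  expect_equal(nrow(merged), 1)
  ## merged position is the intensity-weighted mean
  expect_equal(mzAxis(merged), (400.0000 * 10 + 400.0010 * 30) / 40)
  split2 <- buildCommonAxis(list(a, b), mergeTolPpm = 1)
  expect_equal(nrow(split2), 2)
  expect_error(buildCommonAxis(list()), "empty")
})

test_that("the union axis of a cohort far exceeds any single peak list", {
  sp <- generateCohort(smallCohortConfig(seed = 4))
  fm <- buildCommonAxis(sp)
  perSample <- vapply(sp, function(s) length(mzAxis(s)), integer(1))
  ## per-sample decoy positions are unique, so the union axis dwarfs any
  ## one sample (the real-data analogue: 16540 columns for 76 samples)
  expect_gt(nrow(fm), 5 * max(perSample))
  expect_equal(ncol(fm), 76)
})

test_that("sample order only permutes rows of the assembled matrix", {
  sp <- generateCohort(smallCohortConfig(seed = 9))[1:6]
  fm1 <- buildCommonAxis(sp)
  perm <- c(4, 1, 6, 2, 5, 3)
  fm2 <- buildCommonAxis(sp[perm])
  expect_equal(mzAxis(fm1), mzAxis(fm2))
  expect_equal(intensityMatrix(fm1)[perm, ], unname(intensityMatrix(fm2)),
               ignore_attr = TRUE)
})

test_that("row normalisation gives unit sum of squares and is idempotent", {
  fm <- makeFeatureSet(rbind(c(3, 4), c(1, 1)))
  nfm <- normalizeRows(fm)
  expect_equal(intensityMatrix(nfm)[1, ], c(0.6, 0.8), ignore_attr = TRUE)
  expect_true(isNormalized(nfm))
  again <- normalizeRows(nfm)
  expect_equal(intensityMatrix(again), intensityMatrix(nfm),
               tolerance = 1e-12)

  withr::with_seed(3, {
    R <- matrix(stats::runif(10 * 50), 10, 50)
  })
  nr <- intensityMatrix(normalizeRows(makeFeatureSet(R)))
  expect_true(all(abs(rowSums(nr^2) - 1) <= 1e-10))
})

test_that("all-zero samples are refused by name", {
  X <- rbind(c(1, 2), c(0, 0))
  expect_error(normalizeRows(makeFeatureSet(X)), "S002")
})

test_that("ROI keeps exactly the columns exceeding 3% of the global maximum", {
  X <- rbind(c(100, 2, 5), c(50, 1, 4))
  fm <- makeFeatureSet(X, mz = c(310, 320, 330))
  res <- roiSelect(fm, 0.03, force = TRUE)
  expect_equal(res$report@thresholdValue, 3.0)
  expect_equal(res$report@keptIndices, c(1L, 3L))
  expect_equal(mzAxis(res$fm), c(310, 330))
  expect_true(isRoiCompressed(res$fm))
  ## a column exactly at the threshold is dropped (strict "higher than")
  Xeq <- rbind(c(100, 3, 5), c(50, 1, 4))
  expect_equal(roiSelect(makeFeatureSet(Xeq), 0.03,
                         force = TRUE)$report@keptIndices, c(1L, 3L))
})

test_that("a vanishing threshold keeps every nonzero column", {
  X <- rbind(c(5, 0, 2), c(1, 0, 3))
  res <- roiSelect(makeFeatureSet(X), 1e-12, force = TRUE)
  expect_equal(res$report@keptIndices, c(1L, 3L))
  expect_error(roiSelect(makeFeatureSet(X), 0), "between 0 and 1")
  expect_error(roiSelect(makeFeatureSet(X), 1), "between 0 and 1")
})

test_that("ROI equals a brute-force column scan on random matrices", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      X <- matrix(stats::rexp(8 * 40), 8, 40)
      frac <- stats::runif(1, 0.01, 0.5)
    })
    res <- roiSelect(normalizeRows(makeFeatureSet(X)), frac)
    Xn <- X / sqrt(rowSums(X^2))
    keep <- which(apply(Xn, 2, max) > frac * max(Xn))
    expect_equal(res$report@keptIndices, as.integer(keep))
  }
})

test_that("the pipeline order is normalise first, then compress", {
  fm <- makeFeatureSet(rbind(c(1, 2), c(3, 4)))
  expect_error(roiSelect(fm, 0.03), "normalise first")
  expect_no_error(roiSelect(fm, 0.03, force = TRUE))
})

test_that("difference spectrum is NILM minus SIL and flips under label swap", {
  withr::with_seed(6, X <- matrix(stats::runif(6 * 5), 6, 5))
  labs <- c("NILM", "NILM", "NILM", "SIL", "SIL", "SIL")
  fm <- makeFeatureSet(X, labels = labs, normalized = TRUE,
                       roiCompressed = TRUE)
  d <- differenceSpectrum(fm)
  expect_equal(d$difference,
               colMeans(X[1:3, ]) - colMeans(X[4:6, ]),
               ignore_attr = TRUE)
  swapped <- makeFeatureSet(X, labels = rev(labs), normalized = TRUE,
                            roiCompressed = TRUE)
  expect_equal(differenceSpectrum(swapped)$difference, -d$difference)
  ## identical class means give the zero vector
  same <- makeFeatureSet(rbind(X[1:3, ], X[1:3, ]), labels = labs,
                         normalized = TRUE, roiCompressed = TRUE)
  expect_equal(differenceSpectrum(same)$difference, rep(0, 5))
})

test_that("a marker elevated in SIL shows a negative difference entry", {
  sp <- generateCohort(smallCohortConfig(seed = 13))
  fm <- preprocessCohort(sp)
  d <- differenceSpectrum(fm)
  i <- which.min(abs(d$mz - 331.177))
  expect_lt(d$difference[i], 0)
  ## matches a direct group-mean computation on the same matrix
  X <- intensityMatrix(fm)
  labs <- classLabels(fm)
  expect_equal(d$difference[i],
               mean(X[labs == "NILM", i]) - mean(X[labs == "SIL", i]))
})
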
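## Training sets engineered so the class moments are exact round numbers.
oneDimTrain <- function(m1 = 0, m2 = 4, s = 1) {
  list(X = matrix(c(m1 - s, m1, m1 + s, m2 - s, m2, m2 + s), ncol = 1),
       y = c("NILM", "NILM", "NILM", "SIL", "SIL", "SIL"))
}

test_that("LDA is nearest-centroid under equal priors and identity covariance", {
  tr <- oneDimTrain()
  fit <- discriminantFit(tr$X, tr$y, "LDA", priors = "equal")
  ## 1-D, means 0 and 4, unit variance: x = 1 scores 1 and 9 (plus the
  ## shared -2 ln(1/2) prior term), class NILM chosen
  S <- discriminantScore(fit, matrix(1))
  expect_equal(as.numeric(S), c(1, 9) - 2 * log(0.5))
  expect_equal(discriminantPredict(fit, matrix(1))$class, "NILM")
  expect_equal(discriminantPredict(fit, matrix(3))$class, "SIL")
})

test_that("the prior term decides exact midpoints", {
  tr <- oneDimTrain()
  ## training proportions 0.9 / 0.1 via replication
  X <- rbind(tr$X[rep(1:3, 9), , drop = FALSE], tr$X[4:6, , drop = FALSE])
  y <- c(rep("NILM", 27), rep("SIL", 3))
  fit <- discriminantFit(X, y, "LDA")
  expect_equal(fit@stats@priors, c(NILM = 0.9, SIL = 0.1))
  ## x = 2 is equidistant from both means; -2 ln pi favours the 0.9 class
  expect_equal(discriminantPredict(fit, matrix(2))$class, "NILM")
})

test_that("QDA selects by variance at a shared mean and in far tails", {
  ## means both 0; variances 1 and 9; equal priors
  X <- matrix(c(-1, 0, 1, -3, 0, 3), ncol = 1)
  y <- c("NILM", "NILM", "NILM", "SIL", "SIL", "SIL")
  fit <- discriminantFit(X, y, "QDA", priors = "equal")
  S0 <- discriminantScore(fit, matrix(0))
  expect_equal(as.numeric(S0), c(log(1), log(9)) - 2 * log(0.5))
  expect_equal(discriminantPredict(fit, matrix(0))$class, "NILM")
  ## deep in the tail the heavy-variance class wins: 36 + 0 > 4 + ln 9
  expect_equal(discriminantPredict(fit, matrix(6))$class, "SIL")
})

test_that("QDA with equal class covariances decides exactly like LDA", {
  withr::with_seed(11, {
    base <- matrix(stats::rnorm(20 * 3), 20, 3)
    Z <- matrix(stats::rnorm(40 * 3), 40, 3)
  })
  ## identical within-class shapes, shifted means
  X <- rbind(base, sweep(base, 2, c(1.5, -1, 0.5), "+"))
  y <- c(rep("NILM", 20), rep("SIL", 20))
  lda <- discriminantFit(X, y, "LDA", priors = "equal")
  qda <- discriminantFit(X, y, "QDA", priors = "equal")
  expect_identical(discriminantPredict(qda, Z)$class,
                   discriminantPredict(lda, Z)$class)
})

test_that("discriminant scores match explicit-inverse brute force", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      X <- matrix(stats::rnorm(30 * 4), 30, 4)
      y <- rep(c("NILM", "SIL"), each = 15)
      X[y == "SIL", ] <- X[y == "SIL", ] + 1
      Z <- matrix(stats::rnorm(5 * 4), 5, 4)
    })
    st <- classStats(X, y)
    for (kind in c("LDA", "QDA")) {
      fit <- discriminantFit(X, y, kind)
      S <- discriminantScore(fit, Z)
      for (k in c("NILM", "SIL")) {
        Sig <- if (kind == "LDA") st@pooled else st@perClass[[k]]
        Si <- solve(Sig)
        for (i in 1:5) {
          d <- Z[i, ] - st@means[[k]]
          expected <- as.numeric(t(d) %*% Si %*% d) -
            2 * log(st@priors[[k]]) +
            if (kind == "QDA") as.numeric(determinant(Sig)$modulus) else 0
          expect_equal(unname(S[i, k]), expected, tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("kernel formulas match their closed forms", {
  x <- c(1, 2)
  z <- c(3, 4)
  expect_equal(kernelEval(kernelSpec("linear"), x, z), 11)
  expect_equal(kernelEval(kernelSpec("quadratic", tau = 0), x, z), 121)
  expect_equal(kernelEval(kernelSpec("quadratic", tau = 2), x, z), 169)
  expect_equal(kernelEval(kernelSpec("poly3", tau = 0), x, z), 11^3)
  expect_equal(kernelEval(kernelSpec("rbf", gamma = 0.25), x, x), 1)
  expect_equal(kernelEval(kernelSpec("rbf", gamma = 0.25), x, z),
               exp(-0.25 * 8))
  ## orthogonal vectors under the MLP kernel with k2 = 0: tanh(0) = 0
  expect_equal(kernelEval(kernelSpec("mlp", k1 = 1, k2 = 0),
                          c(1, 0), c(0, 1)), 0)
  expect_error(kernelEval(kernelSpec("linear"), c(1, 2), c(1, 2, 3)),
               "equal length")
  expect_error(kernelSpec("rbf", gamma = -1), "gamma")
  expect_error(kernelSpec("quadratic", tau = -1), "tau")
})

test_that("RBF Gram matrices are symmetric positive semi-definite", {
  for (seed in 1:5) {
    withr::with_seed(seed, X <- matrix(stats::rnorm(15 * 4), 15, 4))
    K <- kernelMatrix(kernelSpec("rbf", gamma = 0.7), X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

svmToy <- function() {
  list(X = rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1)),
       y = c(-1, -1, 1, 1))
}

test_that("the 4-point toy has its max-margin boundary at x1 = 1", {
  toy <- svmToy()
  m <- svmTrain(toy$X, toy$y, kernelSpec("linear"), C = 100)
  ## boundary point scores zero; training side scores have the right sign
  expect_equal(svmDecision(m, c(1, 0.5))$score, 0, tolerance = 1e-6)
  expect_equal(svmDecision(m, toy$X)$score, toy$y, tolerance = 1e-6)
  expect_equal(svmDecision(m, c(0.5, 0))$score, -0.5, tolerance = 1e-6)
  expect_true(m@converged)
})

test_that("separable training data are fitted without training errors", {
  withr::with_seed(21, {
    X <- rbind(matrix(stats::rnorm(30, 0, 0.4), 15, 2),
               matrix(stats::rnorm(30, 3, 0.4), 15, 2))
  })
  y <- rep(c(-1, 1), each = 15)
  m <- svmTrain(X, y, kernelSpec("linear"), C = 1000)
  expect_equal(sign(svmDecision(m, X)$score), y)
})

test_that("every fit satisfies dual feasibility and KKT conditions", {
  specs <- list(kernelSpec("linear"), kernelSpec("quadratic"),
                kernelSpec("poly3"), kernelSpec("rbf", gamma = 0.5))
  for (seed in 1:6) {
    withr::with_seed(seed, {
      X <- matrix(stats::rnorm(24 * 3), 24, 3)
      y <- rep(c(-1, 1), each = 12)
      X[y == 1, ] <- X[y == 1, ] + 1
      C <- sample(c(0.5, 1, 10), 1)
    })
    spec <- specs[[(seed %% length(specs)) + 1]]
    m <- svmTrain(X, y, spec, C = C)
    expect_true(all(m@alpha >= 0 & m@alpha <= C + 1e-8))
    expect_lt(abs(sum(m@alpha * m@y)), 1e-8)
    ## KKT: margin SVs sit on the margin; bound SVs inside/outside it
    f <- svmDecision(m, m@supportVectors)$score
    marg <- m@alpha < C - 1e-6
    expect_true(all(abs(m@y[marg] * f[marg] - 1) < 1e-3))
    expect_true(all(m@y[!marg] * f[!marg] <= 1 + 1e-3))
  }
})

test_that("negating the training labels negates every decision score", {
  withr::with_seed(31, {
    X <- matrix(stats::rnorm(20 * 2), 20, 2)
    y <- rep(c(-1, 1), 10)
    Z <- matrix(stats::rnorm(10), 5, 2)
  })
  a <- svmTrain(X, y, kernelSpec("rbf", gamma = 1), C = 2, tol = 1e-8)
  b <- svmTrain(X, -y, kernelSpec("rbf", gamma = 1), C = 2, tol = 1e-8)
  expect_equal(svmDecision(a, Z)$score, -svmDecision(b, Z)$score,
               tolerance = 1e-6)
})

test_that("labelled input maps SIL to +1 and scores margin SVs near their label", {
  tr <- oneDimTrain()
  m <- svmTrain(tr$X, tr$y, kernelSpec("linear"), C = 10)
  pr <- svmDecision(m, matrix(c(-1, 5), ncol = 1))
  expect_equal(pr$class, c("NILM", "SIL"))
  marg <- m@alpha < m@cost - 1e-6
  f <- svmDecision(m, m@supportVectors)$score
  expect_true(all(abs(f[marg] - m@y[marg]) < 1e-3))
})

test_that("KNN takes the majority of the k nearest and needs odd k", {
  Xtr <- matrix(c(0, 1, 2, 10), ncol = 1)
  ytr <- c("NILM", "NILM", "SIL", "SIL")
  ## k = 1 at a training point returns that point's label
  expect_equal(knnClassify(Xtr, ytr, matrix(2), k = 1)$class, "SIL")
  ## 3 nearest of x = 0.5 are labelled (NILM, NILM, SIL) -> NILM
  r <- knnClassify(Xtr, ytr, matrix(0.5), k = 3)
  expect_equal(r$class, "NILM")
  expect_equal(r$score, 1 / 3)
  expect_error(knnClassify(Xtr, ytr, matrix(1), k = 2), "odd")
  expect_error(knnClassify(Xtr, ytr, matrix(1), k = 5), "training size")
})

test_that("validation-chosen k maximises balanced accuracy, smallest on ties", {
  d <- makePlantedCohort(17, nPerClass = 40, p = 10, shift = 1.5)
  kGrid <- c(1, 3, 5, 7)
  chosen <- knnSelectK(d$X[d$train, ], d$labels[d$train],
                       d$X[d$validation, ], d$labels[d$validation], kGrid)
  bacc <- sapply(kGrid, function(k) {
    pred <- knnClassify(d$X[d$train, ], d$labels[d$train],
                        d$X[d$validation, ], k = k)$class
    yv <- d$labels[d$validation]
    (mean(pred[yv == "SIL"] == "SIL") +
       mean(pred[yv == "NILM"] == "NILM")) / 2
  })
  expect_equal(chosen, kGrid[which.max(bacc)])
  expect_equal(bacc[kGrid == chosen], max(bacc))
})

test_that("SMO solutions agree with an independent SVM implementation", {
  suppressPackageStartupMessages(library(e1071))
  withr::with_seed(41, {
    X <- matrix(stats::rnorm(40 * 4), 40, 4)
    y <- rep(c(-1, 1), each = 20)
    X[y == 1, ] <- X[y == 1, ] + 1.2
    Z <- matrix(stats::rnorm(12 * 4), 12, 4)
  })
  for (C in c(1, 10)) {
    mine <- svmTrain(X, y, kernelSpec("rbf", gamma = 0.3), C = C,
                     tol = 1e-6)
    ref <- e1071::svm(X, factor(y), kernel = "radial", gamma = 0.3,
                      cost = C, scale = FALSE)
    refScore <- attr(predict(ref, Z, decision.values = TRUE),
                     "decision.values")[, 1]
    ## e1071 orients its decision values by its first factor level
    orient <- sign(stats::cor(refScore, svmDecision(mine, Z)$score))
    expect_equal(svmDecision(mine, Z)$score, unname(orient * refScore),
                 tolerance = 1e-3)
  }
})

test_that("LDA class decisions agree with MASS::lda under matching priors", {
  withr::with_seed(43, {
    X <- matrix(stats::rnorm(60 * 3), 60, 3)
    y <- rep(c("NILM", "SIL"), each = 30)
    X[y == "SIL", ] <- X[y == "SIL", ] + 0.8
    Z <- matrix(stats::rnorm(30 * 3), 30, 3)
  })
  mine <- discriminantPredict(discriminantFit(X, y, "LDA"), Z)$class
  ref <- as.character(stats::predict(MASS::lda(X, grouping = y), Z)$class)
  expect_identical(mine, ref)
})
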
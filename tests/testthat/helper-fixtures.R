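## Shared fixtures, all generated in code.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

## A LipidFeatureSet built directly from a samples-by-features matrix,
## bypassing the common-axis builder, for unit tests of downstream stages.
makeFeatureSet <- function(X, mz = seq_len(ncol(X)) + 300,
                           labels = rep(c("NILM", "SIL"),
                                        length.out = nrow(X)),
                           normalized = FALSE, roiCompressed = FALSE) {
  se <- SummarizedExperiment(
    assays = list(intensity = t(X)),
    rowData = S4Vectors::DataFrame(mz = mz),
    colData = S4Vectors::DataFrame(
      sample_id = sprintf("S%03d", seq_len(nrow(X))),
      label = labels
    ),
    metadata = list(flags = list(normalized = normalized,
                                 roiCompressed = roiCompressed))
  )
  new("LipidFeatureSet", se)
}

## A small, fast synthetic cohort configuration for pipeline-level tests.
smallCohortConfig <- function(seed = 1, effectSize = 5, ...) {
  cohortConfig(nBackgroundPeaks = 60, nDecoyPeaks = 40,
               markerTable = defaultMarkerTable(effectSize),
               seed = seed, ...)
}

## Preprocess a cohort up to the compressed matrix.
preprocessCohort <- function(spectra, mergeTolPpm = 5, fraction = 0.03) {
  roiSelect(normalizeRows(buildCommonAxis(spectra, mergeTolPpm)),
            fraction)$fm
}

## Planted-informative-variable cohort: two of p standard-normal variables
## carry complementary class separation (each shifts the SIL class by
## `shift` standard deviations in its own coordinate, so the pair - not
## either variable alone - minimises the validation Mahalanobis risk).
## Returns the matrix plus a Kennard-Stone 70/15/15 split computed per
## class.
makePlantedCohort <- function(seed, nPerClass = 150, p = 50, shift = 2,
                              planted = NULL) {
  if (is.null(planted)) {
    planted <- if (p >= 31) c(7L, 31L) else c(3L, p - 2L)
  }
  withr::with_seed(seed, {
    n <- 2 * nPerClass
    X <- matrix(stats::rnorm(n * p), n, p)
    lab <- c(rep("NILM", nPerClass), rep("SIL", nPerClass))
    for (j in planted) X[lab == "SIL", j] <- X[lab == "SIL", j] + shift
    ord1 <- kennardStoneOrder(X[seq_len(nPerClass), , drop = FALSE])
    ord2 <- nPerClass +
      kennardStoneOrder(X[nPerClass + seq_len(nPerClass), , drop = FALSE])
    nv <- floor(0.15 * nPerClass)
    nt <- nPerClass - 2 * nv
    list(X = X, labels = lab, planted = planted,
         train = c(ord1[seq_len(nt)], ord2[seq_len(nt)]),
         validation = c(ord1[nt + seq_len(nv)], ord2[nt + seq_len(nv)]),
         prediction = c(ord1[nt + nv + seq_len(nv)],
                        ord2[nt + nv + seq_len(nv)]))
  })
}

## Run the preprocessing + split + PCA + one-classifier pipeline on a
## synthetic cohort and return prediction-set confusion counts. Used by
## the stochastic pipeline-recovery tests.
pipelineConfusion <- function(seed, effectSize,
                              features = "pca", classifier = "svm",
                              kernel = "rbf") {
  grid <- data.frame(features = features, classifier = classifier,
                     kernel = kernel, stringsAsFactors = FALSE)
  cfg <- runConfig(
    synthetic = cohortConfig(markerTable = defaultMarkerTable(effectSize)),
    grid = grid, seed = seed)
  out <- runPipeline(cfg, outputDir = tempfile("lc_test_"))
  yt <- classLabels(out$featureSet)[predictionIndices(out$split)]
  confusionCounts(yt, out$predictions[[1]]$class)
}

## Brute-force oracles -----------------------------------------------------

## Exhaustive maximin recomputation of the Kennard-Stone ordering.
bruteKennardStone <- function(X) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  best <- c(NA, NA)
  bestD <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] > bestD) {
        bestD <- D[i, j]
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n) {
    rem <- setdiff(seq_len(n), sel)
    md <- sapply(rem, function(r) min(D[r, sel]))
    sel <- c(sel, rem[which.max(md)])
  }
  as.integer(sel)
}

## Explicit-loop G recomputation (explicit inverse, explicit per-sample
## loop), independent of the package's vectorised path.
bruteFitnessG <- function(selected, Xtr, ytr, Xv, yv) {
  Xt <- Xtr[, selected, drop = FALSE]
  Xvs <- Xv[, selected, drop = FALSE]
  classes <- sort(unique(ytr))
  means <- lapply(classes, function(k) colMeans(Xt[ytr == k, , drop = FALSE]))
  names(means) <- classes
  p <- length(selected)
  acc <- matrix(0, p, p)
  for (k in classes) {
    Xk <- Xt[ytr == k, , drop = FALSE]
    mk <- means[[k]]
    for (i in seq_len(nrow(Xk))) {
      d <- Xk[i, ] - mk
      acc <- acc + outer(d, d)
    }
  }
  S <- acc / (nrow(Xt) - length(classes))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
    S <- S + diag(1e-6 * sum(diag(S)) / p, p)
  }
  Si <- solve(S)
  g <- numeric(nrow(Xvs))
  for (i in seq_len(nrow(Xvs))) {
    r2 <- sapply(classes, function(k) {
      d <- Xvs[i, ] - means[[k]]
      as.numeric(t(d) %*% Si %*% d)
    })
    own <- r2[[yv[i]]]
    wrong <- min(r2[names(r2) != yv[i]])
    g[i] <- if (own == 0) 0 else own / wrong
  }
  mean(g)
}

## Mann-Whitney AUC by exhaustive pair counting, ties counted one half.
bruteMannWhitneyAuc <- function(scores, yTrue) {
  pos <- scores[yTrue == "SIL"]
  neg <- scores[yTrue == "NILM"]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}
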
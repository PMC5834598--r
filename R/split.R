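## Deterministic Kennard-Stone sample splitting.

#' Kennard-Stone maximin ordering of samples
#'
#' Classical Kennard-Stone selection on the Euclidean metric between rows:
#' the first two selections are the pair at maximum pairwise distance
#' (lower index first; ties broken toward the lowest indices), and every
#' subsequent selection maximises its minimum distance to all samples
#' already selected (ties again toward the lowest index). Entirely
#' deterministic.
#'
#' @param X numeric samples-by-features matrix, `nrow(X) >= 2`.
#' @return Integer permutation of `1:nrow(X)`, most design-spanning samples
#'   first.
#' @examples
#' kennardStoneOrder(matrix(c(0, 1, 10)))  # starts with the farthest pair
#' @export
kennardStoneOrder <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("Kennard-Stone requires at least 2 samples", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  ## farthest pair, lowest indices on ties
  m <- max(D)
  hits <- which(D >= m, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])
  remaining <- setdiff(seq_len(n), sel)
  minD <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(remaining) > 0) {
    best <- remaining[which.max(minD[remaining])]  # which.max: first = lowest
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
    minD <- pmin(minD, D[, best])
  }
  sel
}

#' Split a cohort 70/15/15 by Kennard-Stone
#'
#' Partitions the samples of a normalised, ROI-compressed
#' [LipidFeatureSet-class] into training, validation and prediction sets.
#' With `stratified = TRUE` (the default) the Kennard-Stone ordering is
#' computed within each class: the validation set takes
#' `floor(f_val * n_c)` samples per class, the prediction set the next
#' `floor(f_pred * n_c)`, and the training set the remainder, with the
#' Kennard-Stone-earliest (most design-spanning) samples assigned to
#' training. On the 42 + 34 study design this yields 54/11/11 overall and a
#' prediction set of 6 NILM + 5 SIL.
#'
#' @param fm a normalised, ROI-compressed [LipidFeatureSet-class] (the
#'   matrix the classifiers will see; distances are computed on it).
#' @param stratified run Kennard-Stone per class (default) or globally.
#' @param fractions numeric(3) train/validation/prediction fractions
#'   summing to 1 (default `c(0.70, 0.15, 0.15)`).
#' @param enforceFlags set FALSE to split a matrix that has not been
#'   normalised and ROI-compressed.
#' @return A [SplitIndices-class].
#' @export
splitKennardStone <- function(fm, stratified = TRUE,
                              fractions = c(0.70, 0.15, 0.15),
                              enforceFlags = TRUE) {
  stopifnot(is(fm, "LipidFeatureSet"))
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L) {
    stop("fractions must be three values summing to 1", call. = FALSE)
  }
  if (enforceFlags && (!isNormalized(fm) || !isRoiCompressed(fm))) {
    stop("split expects a normalised, ROI-compressed matrix", call. = FALSE)
  }
  X <- intensityMatrix(fm)
  labs <- classLabels(fm)
  groups <- if (stratified) split(seq_len(nrow(X)), labs) else
    list(all = seq_len(nrow(X)))
  tr <- va <- pr <- integer()
  for (idx in groups) {
    nc <- length(idx)
    if (nc < 3) {
      stop("each split group needs at least 3 samples, got ", nc,
           call. = FALSE)
    }
    nv <- floor(fractions[2] * nc)
    np <- floor(fractions[3] * nc)
    nt <- nc - nv - np
    ord <- idx[kennardStoneOrder(X[idx, , drop = FALSE])]
    tr <- c(tr, ord[seq_len(nt)])
    va <- c(va, ord[nt + seq_len(nv)])
    pr <- c(pr, ord[nt + nv + seq_len(np)])
  }
  new("SplitIndices",
      train = as.integer(sort(tr)), validation = as.integer(sort(va)),
      prediction = as.integer(sort(pr)), fractions = as.numeric(fractions))
}

#' Serialise a split to CSV for audit
#'
#' @param split A [SplitIndices-class].
#' @param fm the [LipidFeatureSet-class] the split indexes into.
#' @param path output CSV path (`sample_id,set`).
#' @return Invisibly, `path`.
#' @export
writeSplit <- function(split, fm, path) {
  ids <- sampleIds(fm)
  df <- rbind(
    data.frame(sample_id = ids[split@train], set = "training"),
    data.frame(sample_id = ids[split@validation], set = "validation"),
    data.frame(sample_id = ids[split@prediction], set = "prediction")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
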
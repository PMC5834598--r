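## k-nearest-neighbour classification on the full spectral matrix.

#' Classify by k nearest neighbours
#'
#' Euclidean-distance majority vote over the k nearest training samples.
#' Only odd k are accepted, which rules out vote ties in the two-class
#' setting. The SIL vote fraction is returned as a continuous score for
#' ROC analysis.
#'
#' @param Xtrain,yTrain training matrix (samples x features) and
#'   NILM/SIL labels.
#' @param Z query matrix (or single vector).
#' @param k odd neighbour count, `k <= nrow(Xtrain)`.
#' @return list with `class` and `score` (SIL vote fraction in [0, 1]).
#' @export
knnClassify <- function(Xtrain, yTrain, Z, k = 3) {
  Xtrain <- as.matrix(Xtrain)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  Z <- as.matrix(Z)
  if (k %% 2 == 0) stop("k must be odd to avoid vote ties", call. = FALSE)
  if (k > nrow(Xtrain)) stop("k exceeds the training size", call. = FALSE)
  yTrain <- assertLabels(yTrain)
  d2 <- outer(rowSums(Z^2), rowSums(Xtrain^2), "+") -
    2 * Z %*% t(Xtrain)
  frac <- apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    mean(yTrain[nb] == .posLabel)
  })
  list(class = ifelse(frac > 0.5, .posLabel, .negLabel),
       score = as.numeric(frac))
}

#' Choose k on the validation set
#'
#' Evaluates every odd k in `kGrid` on the validation samples and returns
#' the one maximising balanced accuracy (mean of sensitivity and
#' specificity); ties go to the smallest k.
#'
#' @inheritParams knnClassify
#' @param Xval,yVal validation matrix and labels.
#' @param kGrid candidate odd k values (default `c(1, 3, 5, 7, 9)`).
#' @return The selected k.
#' @export
knnSelectK <- function(Xtrain, yTrain, Xval, yVal,
                       kGrid = c(1, 3, 5, 7, 9)) {
  kGrid <- sort(unique(kGrid[kGrid <= nrow(as.matrix(Xtrain))]))
  if (length(kGrid) == 0) stop("no feasible k in grid", call. = FALSE)
  yVal <- assertLabels(yVal)
  bacc <- vapply(kGrid, function(k) {
    pred <- knnClassify(Xtrain, yTrain, Xval, k = k)$class
    sens <- mean(pred[yVal == .posLabel] == .posLabel)
    spec <- mean(pred[yVal == .negLabel] == .negLabel)
    (sens + spec) / 2
  }, numeric(1))
  kGrid[which.max(bacc)]  # which.max takes the first maximum: smallest k
}
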
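## Principal component analysis by centred SVD.

#' Fit a principal component model on training data
#'
#' Column-mean-centred singular value decomposition of the training matrix.
#' No variance scaling is applied (samples are already unit-norm). Each
#' loading's sign is fixed so that its largest-magnitude entry is positive.
#' The default of ten components matches the number of score variables fed
#' to the downstream classifiers.
#'
#' @param X numeric samples-by-features training matrix.
#' @param k number of components (default 10); must satisfy
#'   `k <= min(nrow(X) - 1, ncol(X))`.
#' @return A [PCAModel-class].
#' @export
pcaFit <- function(X, k = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (k > min(n - 1, p)) {
    stop("k must not exceed min(n - 1, p) = ", min(n - 1, p), call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = k)
  L <- sv$v
  ## sign convention: largest-|.| entry of each loading positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  evfrac <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  new("PCAModel", center = ctr, loadings = L,
      explainedVarianceFraction = evfrac, k = as.integer(k))
}

#' Project data onto a fitted principal component model
#'
#' @param model A [PCAModel-class].
#' @param X numeric samples-by-features matrix on the same feature axis the
#'   model was fitted on.
#' @return n x k score matrix.
#' @export
pcaScores <- function(model, X) {
  stopifnot(is(model, "PCAModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@center)) {
    stop("feature dimension mismatch: model has ", length(model@center),
         ", data has ", ncol(X), call. = FALSE)
  }
  sweep(X, 2, model@center) %*% model@loadings
}

#' @describeIn pcaFit Explained-variance fractions of a fitted model.
#' @export
explainedVariance <- function(model) model@explainedVarianceFraction
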
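## Linear and quadratic discriminant classifiers with the minimum-score
## decision rule.

#' Fit a linear or quadratic discriminant model
#'
#' LDA uses the pooled within-class covariance for every class; QDA keeps a
#' separate covariance per class and adds its log-determinant to the score.
#' Priors default to the training class proportions.
#'
#' @param X numeric samples-by-features training matrix.
#' @param labels per-row class labels.
#' @param kind `"LDA"` or `"QDA"`.
#' @param priors `"proportions"` or `"equal"`.
#' @return A [DiscriminantModel-class].
#' @export
discriminantFit <- function(X, labels, kind = c("LDA", "QDA"),
                            priors = c("proportions", "equal")) {
  kind <- match.arg(kind)
  new("DiscriminantModel", kind = kind,
      stats = classStats(X, labels, match.arg(priors)))
}

#' Discriminant classification scores
#'
#' For LDA the score of sample i against class k is the squared Mahalanobis
#' distance to the class mean under the pooled covariance minus twice the
#' log prior:
#' \deqn{L_{ik} = (x_i - \bar{x}_k)^T \Sigma_{pooled}^{-1} (x_i - \bar{x}_k)
#'   - 2 \ln \pi_k.}
#' For QDA the per-class covariance replaces the pooled one and the
#' log-determinant of that covariance is added:
#' \deqn{Q_{ik} = (x_i - \bar{x}_k)^T \Sigma_k^{-1} (x_i - \bar{x}_k)
#'   + \ln |\Sigma_k| - 2 \ln \pi_k.}
#' The predicted class minimises the score.
#'
#' @param model a fitted [DiscriminantModel-class].
#' @param X numeric samples-by-features matrix to score.
#' @return n x K matrix of scores, columns named by class.
#' @export
discriminantScore <- function(model, X) {
  stopifnot(is(model, "DiscriminantModel"))
  st <- model@stats
  if (length(st@classes) == 0) stop("unfitted model", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(dim(X)) || ncol(X) != length(st@means[[1]])) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  out <- sapply(st@classes, function(k) {
    if (model@kind == "LDA") {
      mahalanobisSq(X, st@means[[k]], st@pooled) - 2 * log(st@priors[[k]])
    } else {
      S <- regularizeCovariance(st@perClass[[k]])
      ld <- determinant(S, logarithm = TRUE)
      mahalanobisSq(X, st@means[[k]], S) + as.numeric(ld$modulus) -
        2 * log(st@priors[[k]])
    }
  })
  matrix(out, nrow = nrow(X), dimnames = list(NULL, st@classes))
}

#' Classify by minimum discriminant score
#'
#' Returns, per sample, the argmin class together with a signed score for
#' ROC analysis oriented so that larger values are more SIL-like
#' (score = L_NILM - L_SIL: positive when the sample is closer to the SIL
#' class).
#'
#' @inheritParams discriminantScore
#' @return list with `class` (character), `score` (numeric, SIL-oriented)
#'   and `scores` (the full score matrix).
#' @export
discriminantPredict <- function(model, X) {
  S <- discriminantScore(model, X)
  cls <- colnames(S)[apply(S, 1, which.min)]
  rocScore <- if (all(c("NILM", "SIL") %in% colnames(S))) {
    S[, "NILM"] - S[, "SIL"]
  } else {
    -apply(S, 1, min)
  }
  list(class = cls, score = as.numeric(rocScore), scores = S)
}
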
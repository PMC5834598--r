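## Model evaluation: confusion counts, sensitivity, specificity, the
## harmonic-mean F-score and ROC AUC. SIL is the positive class throughout.

#' Confusion counts for a two-class prediction
#'
#' @param yTrue,yPred equal-length NILM/SIL label vectors; SIL is the
#'   positive class.
#' @return named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusionCounts(c("SIL", "NILM"), c("SIL", "SIL"))
#' @export
confusionCounts <- function(yTrue, yPred) {
  yTrue <- assertLabels(yTrue)
  yPred <- assertLabels(yPred)
  if (length(yTrue) != length(yPred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  c(TP = sum(yTrue == .posLabel & yPred == .posLabel),
    TN = sum(yTrue == .negLabel & yPred == .negLabel),
    FP = sum(yTrue == .negLabel & yPred == .posLabel),
    FN = sum(yTrue == .posLabel & yPred == .negLabel))
}

#' Sensitivity and specificity in percent
#'
#' Sensitivity = TP / (TP + FN) x 100; specificity = TN / (TN + FP) x 100.
#' A zero denominator raises an error rather than silently returning 0.
#'
#' @param cc confusion counts from [confusionCounts()].
#' @return percentage in [0, 100].
#' @export
sensitivity <- function(cc) {
  den <- cc[["TP"]] + cc[["FN"]]
  if (den == 0) stop("sensitivity undefined: no positive samples",
                     call. = FALSE)
  cc[["TP"]] / den * 100
}

#' @rdname sensitivity
#' @export
specificity <- function(cc) {
  den <- cc[["TN"]] + cc[["FP"]]
  if (den == 0) stop("specificity undefined: no negative samples",
                     call. = FALSE)
  cc[["TN"]] / den * 100
}

#' Harmonic-mean F-score of sensitivity and specificity
#'
#' F = 2 * SENS * SPEC / (SENS + SPEC), evaluated on the percent scale and
#' reported divided by 100 so the result lies in [0, 1]. This is the
#' sensitivity-specificity harmonic mean used in chemometric model tables,
#' not the precision-recall F1. F(0, 0) is defined as 0 by continuity.
#'
#' @param sens,spec sensitivity and specificity in percent.
#' @return value in [0, 1].
#' @examples
#' fScore(80, 83.3)  # 0.816...
#' @export
fScore <- function(sens, spec) {
  if (sens + spec == 0) return(0)
  (2 * sens * spec / (sens + spec)) / 100
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area under the ROC curve of a continuous score oriented so
#' that larger values are more SIL-like. Tied scores contribute through the
#' trapezoid over the tie block, making the result identical to the
#' Mann-Whitney probability estimate with ties counted one half.
#'
#' @param scores numeric decision scores, larger = more SIL-like.
#' @param yTrue NILM/SIL labels.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c("SIL", "NILM", "SIL", "NILM"))  # 0.75
#' @export
rocAuc <- function(scores, yTrue) {
  yTrue <- assertLabels(yTrue)
  if (length(scores) != length(yTrue)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  P <- sum(yTrue == .posLabel)
  N <- sum(yTrue == .negLabel)
  if (P == 0 || N == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- yTrue[ord] == .posLabel
  ## one ROC vertex per distinct threshold
  lastOfBlock <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(pos)[lastOfBlock] / P)
  fpr <- c(0, cumsum(!pos)[lastOfBlock] / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Assemble an evaluation report over fitted models
#'
#' One row per model, mirroring the published table layout: sensitivity
#' and specificity in percent (1 decimal), AUC and F-score on the unit
#' scale (3 decimals). The F-score column is recomputed from the rounded
#' displayed sensitivity/specificity so the table is internally
#' consistent. Undefined metrics (for example AUC when the prediction set
#' is single-class) are reported as NA.
#'
#' @param predictions named list; each element a list with `class`
#'   (predicted labels) and `score` (SIL-oriented decision scores) for the
#'   prediction samples.
#' @param yTrue true labels of the prediction samples.
#' @param digitsPercent,digitsUnit display rounding (defaults 1 and 3).
#' @return data.frame with columns `model`, `sensitivity`, `specificity`,
#'   `auc`, `f_score`.
#' @export
buildReport <- function(predictions, yTrue, digitsPercent = 1,
                        digitsUnit = 3) {
  yTrue <- assertLabels(yTrue)
  rows <- lapply(names(predictions), function(nm) {
    pr <- predictions[[nm]]
    cc <- confusionCounts(yTrue, pr$class)
    sens <- tryCatch(round(sensitivity(cc), digitsPercent),
                     error = function(e) NA_real_)
    spec <- tryCatch(round(specificity(cc), digitsPercent),
                     error = function(e) NA_real_)
    auc <- tryCatch(round(rocAuc(pr$score, yTrue), digitsUnit),
                    error = function(e) NA_real_)
    fs <- if (is.na(sens) || is.na(spec)) NA_real_ else
      round(fScore(sens, spec), digitsUnit)
    data.frame(model = nm, sensitivity = sens, specificity = spec,
               auc = auc, f_score = fs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
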
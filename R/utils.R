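## Internal helpers shared across modules.

#' Run an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded generators inside the
#' package do not disturb the caller's random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Ridge-regularise an ill-conditioned covariance matrix
#'
#' Adds `lambda * I` with `lambda = 1e-6 * trace(S) / p` whenever the
#' 2-norm condition number exceeds `maxCondition`. Subsets selected by the
#' genetic algorithm can transiently exceed the training sample size, so the
#' discriminant and fitness code routes every covariance through this guard.
#'
#' @param S Symmetric covariance matrix.
#' @param maxCondition Condition-number threshold beyond which the ridge is
#'   applied (default `1e10`).
#' @return A covariance matrix safe to invert.
#' @keywords internal
#' @noRd
regularizeCovariance <- function(S, maxCondition = 1e10) {
  S <- as.matrix(S)
  p <- ncol(S)
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) rep(NA_real_, p))
  lambda <- 1e-6 * sum(diag(S)) / p
  if (!all(is.finite(ev))) {
    return(S + diag(lambda, p))
  }
  emax <- max(ev)
  emin <- min(ev)
  if (emin <= 0 || (emax / emin) > maxCondition) {
    S <- S + diag(lambda, p)
  }
  S
}

## Two-level class labels used throughout: SIL is the positive class.
.posLabel <- "SIL"
.negLabel <- "NILM"

#' Check a label vector is over the NILM/SIL two-level scheme
#' @keywords internal
#' @noRd
assertLabels <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), c(.negLabel, .posLabel))
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected NILM or SIL)", call. = FALSE)
  }
  invisible(as.character(labels))
}
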
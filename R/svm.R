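## Soft-margin support vector machine: five kernels and a deterministic
## SMO solver for the dual problem.

#' Construct a kernel specification
#'
#' @param name one of `"linear"`, `"quadratic"`, `"poly3"`, `"rbf"`,
#'   `"mlp"`.
#' @param tau offset of the quadratic/cubic kernels, `tau >= 0`
#'   (default 1).
#' @param gamma RBF width, `gamma > 0`; defaults to `1 / nFeatures` when
#'   fitted if left `NA`.
#' @param k1,k2 MLP (sigmoid) kernel constants; the classic convention
#'   `k1 = 1, k2 = -1` is the default. This kernel is indefinite, so SVM
#'   training under it may legitimately fail to converge.
#' @return A validated [KernelSpec-class].
#' @examples
#' kernelSpec("rbf", gamma = 0.5)
#' @export
kernelSpec <- function(name = c("linear", "quadratic", "poly3", "rbf",
                                "mlp"),
                       tau = 1, gamma = NA_real_, k1 = 1, k2 = -1) {
  name <- match.arg(name)
  if (name == "rbf" && !is.na(gamma) && gamma <= 0) {
    stop("gamma must be > 0 for the RBF kernel", call. = FALSE)
  }
  if (name %in% c("quadratic", "poly3") && (is.na(tau) || tau < 0)) {
    stop("tau must be >= 0 for polynomial kernels", call. = FALSE)
  }
  new("KernelSpec", name = name, tau = tau,
      gamma = if (name == "rbf") gamma else NA_real_, k1 = k1, k2 = k2)
}

#' Evaluate a kernel
#'
#' `kernelEval()` computes k(x, z) for two vectors; `kernelMatrix()` the
#' full Gram matrix between the rows of two matrices.
#'
#' @param spec A [KernelSpec-class].
#' @param x,z equal-length numeric vectors.
#' @return scalar kernel value.
#' @examples
#' kernelEval(kernelSpec("linear"), c(1, 2), c(3, 4))        # 11
#' kernelEval(kernelSpec("quadratic", tau = 0), c(1, 2), c(3, 4))  # 121
#' @export
kernelEval <- function(spec, x, z) {
  if (length(x) != length(z)) {
    stop("x and z must have equal length", call. = FALSE)
  }
  as.numeric(kernelMatrix(spec, matrix(x, nrow = 1), matrix(z, nrow = 1)))
}

#' @rdname kernelEval
#' @param X,Z numeric matrices with observations in rows.
#' @export
kernelMatrix <- function(spec, X, Z = X) {
  stopifnot(is(spec, "KernelSpec"))
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  G <- X %*% t(Z)
  switch(spec@name,
    linear = G,
    quadratic = (spec@tau + G)^2,
    poly3 = (spec@tau + G)^3,
    rbf = {
      if (is.na(spec@gamma)) {
        stop("RBF kernel requires gamma", call. = FALSE)
      }
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-spec@gamma * d2)
    },
    mlp = tanh(spec@k1 * G + spec@k2)
  )
}

#' Train a soft-margin SVM by sequential minimal optimisation
#'
#' Solves the two-class soft-margin dual with a deterministic SMO variant
#' using maximal-violating-pair working-set selection (the b_up/b_low
#' optimality criterion), so training involves no randomness. The pairwise
#' updates preserve the equality constraint `sum(alpha * y) = 0` to
#' machine precision, and each multiplier is kept in `[0, C]`. After
#' convergence the bias is recomputed as the average over margin support
#' vectors (`0 < alpha < C`); if none exist it is set at the midpoint of
#' the KKT-feasible interval. For the indefinite MLP kernel the curvature
#' along a working pair can be non-positive; the solver then takes a
#' clipped bound step and may hit its iteration cap, in which case it
#' warns and returns with `converged = FALSE`.
#'
#' @param X numeric samples-by-features training matrix.
#' @param y labels: either signed (-1/+1) or "NILM"/"SIL" (SIL maps
#'   to +1).
#' @param spec A [KernelSpec-class]; an RBF spec with `gamma = NA` gets
#'   `gamma = 1 / ncol(X)`.
#' @param C box constraint (default 1).
#' @param tol KKT tolerance used during optimisation (default 1e-4).
#' @param maxPasses iteration cap on full passes over the training set
#'   (default 500).
#' @return An [SvmModel-class].
#' @export
svmTrain <- function(X, y, spec = kernelSpec("rbf"), C = 1, tol = 1e-4,
                     maxPasses = 500) {
  X <- as.matrix(X)
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    assertLabels(y)
    y <- ifelse(y == .posLabel, 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) != 2) {
    stop("two classes with signed labels (+1/-1) are required",
         call. = FALSE)
  }
  if (spec@name == "rbf" && is.na(spec@gamma)) {
    ## scale-aware default: 1 / (p * Var(X)). On unit-norm spectra a bare
    ## 1/p collapses the Gram matrix toward a constant (entries differ by
    ## O(1e-3)), which degenerates the fit to the majority class.
    v <- stats::var(as.numeric(X))
    spec <- kernelSpec("rbf",
                       gamma = 1 / (ncol(X) * if (v > 0) v else 1))
  }
  n <- nrow(X)
  K <- kernelMatrix(spec, X)
  alpha <- numeric(n)
  ## F_i = sum_j alpha_j y_j K_ij - y_i (gradient, no bias)
  Fvec <- -y

  ## maximal-violating-pair working-set selection (Keerthi's b_up/b_low
  ## criterion): optimal when max_{I_low} F <= min_{I_up} F + 2 tol
  converged <- FALSE
  maxIter <- maxPasses * n
  for (iter in seq_len(maxIter)) {
    iUpSet <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    iLowSet <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    bUp <- min(Fvec[iUpSet])
    bLow <- max(Fvec[iLowSet])
    if (bLow <= bUp + 2 * tol) {
      converged <- TRUE
      break
    }
    i <- which(iUpSet)[which.min(Fvec[iUpSet])]
    j <- which(iLowSet)[which.max(Fvec[iLowSet])]
    yi <- y[i]; yj <- y[j]
    ai <- alpha[i]; aj <- alpha[j]
    s <- yi * yj
    if (s < 0) {
      L <- max(0, aj - ai)
      H <- min(C, C + aj - ai)
    } else {
      L <- max(0, ai + aj - C)
      H <- min(C, ai + aj)
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    ## indefinite kernels can give non-positive curvature: take the bound
    ## step along the same descent direction instead
    if (eta <= 1e-12) eta <- 1e-12
    ajNew <- aj + yj * (Fvec[i] - Fvec[j]) / eta
    ajNew <- min(max(ajNew, L), H)
    if (abs(ajNew - aj) < 1e-14) break  # no progress possible
    aiNew <- ai + s * (aj - ajNew)
    Fvec <- Fvec + yi * (aiNew - ai) * K[, i] + yj * (ajNew - aj) * K[, j]
    alpha[i] <- aiNew
    alpha[j] <- ajNew
  }
  if (!converged) {
    iUpSet <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    iLowSet <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    gap <- max(Fvec[iLowSet]) - min(Fvec[iUpSet])
    warning("SMO did not converge within ", maxIter,
            " pair updates (duality-gap proxy ", format(gap, digits = 3),
            "); returning current iterate", call. = FALSE)
  }

  ## bias from margin support vectors, falling back to the midpoint of the
  ## KKT-feasible interval when every multiplier is at a bound
  g <- as.numeric(K %*% (alpha * y))  # decision values without bias
  margin <- alpha > 1e-8 & alpha < C - 1e-8
  if (any(margin)) {
    b <- mean(y[margin] - g[margin])
  } else {
    iUpSet <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    iLowSet <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    b <- -(min(Fvec[iUpSet]) + max(Fvec[iLowSet])) / 2
  }

  sv <- alpha > 1e-8
  new("SvmModel", supportVectors = X[sv, , drop = FALSE],
      alpha = alpha[sv], y = y[sv], b = b, cost = C, kernel = spec,
      converged = converged)
}

#' SVM decision function
#'
#' Evaluates f(z) = sum_i alpha_i y_i k(x_i, z) + b over the support
#' vectors. The raw (pre-sign) score is exposed for ROC analysis; the
#' predicted class is SIL when f > 0, NILM otherwise.
#'
#' @param model An [SvmModel-class].
#' @param Z numeric samples-by-features matrix (or a single vector).
#' @return list with `score` (raw f values) and `class` ("NILM"/"SIL").
#' @export
svmDecision <- function(model, Z) {
  stopifnot(is(model, "SvmModel"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  Kz <- kernelMatrix(model@kernel, Z, model@supportVectors)
  f <- as.numeric(Kz %*% (model@alpha * model@y)) + model@b
  list(score = f, class = ifelse(f > 0, .posLabel, .negLabel))
}
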
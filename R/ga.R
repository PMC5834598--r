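## Genetic-algorithm variable selection minimising the average risk of
## misclassification G on the validation set.

#' Per-class moments of a labelled training matrix
#'
#' Computes class means, the pooled within-class covariance, per-class
#' covariances and the class priors (training proportions by default).
#'
#' @param X numeric samples-by-features matrix.
#' @param labels per-row class labels.
#' @param priors `"proportions"` (training class frequencies) or `"equal"`.
#' @return A [ClassStats-class].
#' @export
classStats <- function(X, labels, priors = c("proportions", "equal")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  K <- length(classes)
  n <- nrow(X)
  p <- ncol(X)
  means <- list()
  perClass <- list()
  pooledAcc <- matrix(0, p, p)
  for (k in classes) {
    Xk <- X[labels == k, , drop = FALSE]
    nk <- nrow(Xk)
    means[[k]] <- colMeans(Xk)
    Sk <- if (nk > 1) stats::cov(Xk) else matrix(0, p, p)
    perClass[[k]] <- Sk
    pooledAcc <- pooledAcc + (nk - 1) * Sk
  }
  pooled <- pooledAcc / max(n - K, 1)
  pr <- if (priors == "equal") rep(1 / K, K) else
    as.numeric(table(factor(labels, levels = classes))) / n
  names(pr) <- classes
  new("ClassStats", classes = classes, means = means, pooled = pooled,
      perClass = perClass, priors = pr)
}

#' Squared Mahalanobis distance
#'
#' r^2 = (x - m)' Sigma^{-1} (x - m), with the covariance routed through a
#' ridge guard when ill-conditioned.
#'
#' @param x numeric vector, or matrix with observations in rows.
#' @param m centre vector.
#' @param Sigma covariance matrix.
#' @return Non-negative squared distance(s).
#' @examples
#' mahalanobisSq(c(1, 2, 3), c(0, 0, 0), diag(c(1, 4, 9)))  # 3
#' @export
mahalanobisSq <- function(x, m, Sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(m) || ncol(x) != ncol(Sigma)) {
    stop("dimension mismatch between x, m and Sigma", call. = FALSE)
  }
  S <- regularizeCovariance(Sigma)
  d <- sweep(x, 2, m)
  Si <- tryCatch(solve(S), error = function(e) {
    stop("singular covariance (", ncol(S), " variables)", call. = FALSE)
  })
  as.numeric(rowSums((d %*% Si) * d))
}

#' Average risk of misclassification G on a validation set
#'
#' For each validation sample, the risk g_n is the ratio of its squared
#' Mahalanobis distance to its own class mean over its distance to the
#' nearest wrong class mean; G is the mean of g_n over the validation
#' samples. G < 1 indicates validation samples sit nearer their own class.
#' Class moments are computed on the training rows restricted to
#' `selected`; the pooled training covariance is shared across classes by
#' default, with per-class covariances available for the QDA pairing.
#'
#' @param selected strictly increasing variable (column) indices.
#' @param Xtrain,yTrain training matrix and labels.
#' @param Xval,yVal validation matrix and labels.
#' @param covariance `"pooled"` (default) or `"perClass"`.
#' @return G, a non-negative scalar.
#' @export
fitnessG <- function(selected, Xtrain, yTrain, Xval, yVal,
                     covariance = c("pooled", "perClass")) {
  covariance <- match.arg(covariance)
  selected <- as.integer(selected)
  if (length(selected) == 0) stop("no variables selected", call. = FALSE)
  Xt <- as.matrix(Xtrain)[, selected, drop = FALSE]
  Xv <- as.matrix(Xval)[, selected, drop = FALSE]
  st <- classStats(Xt, yTrain)
  classes <- st@classes
  r2 <- sapply(classes, function(k) {
    S <- if (covariance == "pooled") st@pooled else st@perClass[[k]]
    mahalanobisSq(Xv, st@means[[k]], S)
  })
  r2 <- matrix(r2, nrow = nrow(Xv), dimnames = list(NULL, classes))
  yVal <- as.character(yVal)
  g <- vapply(seq_len(nrow(Xv)), function(i) {
    own <- r2[i, yVal[i]]
    wrong <- min(r2[i, setdiff(classes, yVal[i])])
    if (own == 0) 0 else own / wrong
  }, numeric(1))
  mean(g)
}

#' Genetic-algorithm configuration
#'
#' @param nGenerations,population,crossoverProb,mutationProb,nRestarts,initBitProb,maxVariables,seed
#'   see [GAConfig-class] for meanings and defaults.
#' @return A validated [GAConfig-class].
#' @export
gaConfig <- function(nGenerations = 40, population = 80,
                     crossoverProb = 0.60, mutationProb = 0.10,
                     nRestarts = 3, initBitProb = 0.05,
                     maxVariables = 30, seed = 1) {
  cfg <- try(new("GAConfig", nGenerations = nGenerations,
                 population = population, crossoverProb = crossoverProb,
                 mutationProb = mutationProb, nRestarts = nRestarts,
                 initBitProb = initBitProb, maxVariables = maxVariables,
                 seed = seed), silent = TRUE)
  if (inherits(cfg, "try-error")) {
    stop("invalid GA configuration: ", attr(cfg, "condition")$message,
         call. = FALSE)
  }
  cfg
}

## Lean two-class G computation used inside the GA loop. Numerically
## identical to fitnessG() (same moments, same ridge rule) but avoids the
## per-call S4 construction and eigen-decomposition, which dominate the
## cost over tens of thousands of chromosome evaluations.
.fastFitnessG <- function(s, Xtrain, yTrain, Xval, yVal,
                          covariance = "pooled") {
  Xt <- Xtrain[, s, drop = FALSE]
  Xv <- Xval[, s, drop = FALSE]
  classes <- sort(unique(yTrain))
  p <- length(s)
  parts <- lapply(classes, function(k) {
    Xk <- Xt[yTrain == k, , drop = FALSE]
    list(n = nrow(Xk), mean = colMeans(Xk),
         S = if (nrow(Xk) > 1) stats::cov(Xk) else matrix(0, p, p))
  })
  names(parts) <- classes
  n <- nrow(Xt)
  pooled <- Reduce(`+`, lapply(parts, function(q) (q$n - 1) * q$S)) /
    max(n - length(classes), 1)
  r2 <- sapply(classes, function(k) {
    S <- if (covariance == "pooled") pooled else parts[[k]]$S
    S <- regularizeCovariance(S)
    d <- sweep(Xv, 2, parts[[k]]$mean)
    rowSums((d %*% solve(S)) * d)
  })
  r2 <- matrix(r2, nrow = nrow(Xv), dimnames = list(NULL, classes))
  g <- vapply(seq_len(nrow(Xv)), function(i) {
    own <- r2[i, yVal[i]]
    wrong <- min(r2[i, setdiff(classes, yVal[i])])
    if (own == 0) 0 else own / wrong
  }, numeric(1))
  mean(g)
}

## One chromosome's fitness: +Inf above the variable cap or on numerical
## failure, otherwise the validation-set risk G.
.gaFitness <- function(bits, Xtrain, yTrain, Xval, yVal, maxVariables,
                       covariance) {
  s <- which(bits)
  if (length(s) == 0 || length(s) > maxVariables) return(Inf)
  tryCatch(.fastFitnessG(s, Xtrain, yTrain, Xval, yVal, covariance),
           error = function(e) Inf)
}

#' Genetic-algorithm variable selection
#'
#' Binary-chromosome genetic algorithm with one bit per m/z feature:
#' tournament selection (size 2), single-point crossover, per-bit mutation,
#' elitism of the single best chromosome, and fitness equal to the
#' validation-set average misclassification risk [fitnessG()]. Empty
#' chromosomes are repaired by activating one random bit; chromosomes
#' selecting more than `maxVariables` features receive infinite fitness,
#' which keeps covariance estimates well-posed and reproduces the small
#' (tens of variables) subsets typical of this workflow. The algorithm is
#' restarted `nRestarts` times from independent random populations
#' (restart r is seeded with `seed + r - 1`) and the best chromosome over
#' all restarts is returned.
#'
#' @param Xtrain,yTrain training matrix (samples x features) and labels.
#' @param Xval,yVal validation matrix and labels.
#' @param config A [GAConfig-class].
#' @param covariance covariance form passed to [fitnessG()].
#' @return A [GAResult-class].
#' @export
gaSelect <- function(Xtrain, yTrain, Xval, yVal, config = gaConfig(),
                     covariance = c("pooled", "perClass")) {
  covariance <- match.arg(covariance)
  stopifnot(is(config, "GAConfig"))
  validObject(config)
  Xtrain <- as.matrix(Xtrain)
  Xval <- as.matrix(Xval)
  p <- ncol(Xtrain)
  pop <- as.integer(config@population)
  fitOf <- function(bits) {
    .gaFitness(bits, Xtrain, yTrain, Xval, yVal, config@maxVariables,
               covariance)
  }
  repair <- function(bits) {
    if (!any(bits)) bits[sample.int(p, 1)] <- TRUE
    bits
  }
  bestBits <- NULL
  bestFit <- Inf
  history <- vector("list", as.integer(config@nRestarts))
  for (r in seq_len(as.integer(config@nRestarts))) {
    restart <- withSeed(config@seed + r - 1, {
      P <- matrix(stats::runif(pop * p) < config@initBitProb, nrow = pop)
      for (i in seq_len(pop)) P[i, ] <- repair(P[i, ])
      fit <- apply(P, 1, fitOf)
      h <- numeric(as.integer(config@nGenerations))
      for (gen in seq_len(as.integer(config@nGenerations))) {
        elite <- which.min(fit)
        newP <- matrix(FALSE, nrow = pop, ncol = p)
        newP[1, ] <- P[elite, ]
        filled <- 1L
        while (filled < pop) {
          ## tournament selection, size 2
          pick <- function() {
            cand <- sample.int(pop, 2, replace = TRUE)
            cand[which.min(fit[cand])]
          }
          pa <- P[pick(), ]
          pb <- P[pick(), ]
          if (p > 1 && stats::runif(1) < config@crossoverProb) {
            cut <- sample.int(p - 1, 1)
            c1 <- c(pa[seq_len(cut)], pb[(cut + 1):p])
            c2 <- c(pb[seq_len(cut)], pa[(cut + 1):p])
          } else {
            c1 <- pa
            c2 <- pb
          }
          for (child in list(c1, c2)) {
            if (filled >= pop) break
            ## mutation: with probability mutationProb the offspring has one
            ## randomly chosen bit flipped (per-offspring semantics; see the
            ## vignette for why per-bit flipping at this rate is untenable)
            if (config@mutationProb > 0 &&
                stats::runif(1) < config@mutationProb) {
              flip <- sample.int(p, 1)
              child[flip] <- !child[flip]
            }
            filled <- filled + 1L
            newP[filled, ] <- repair(child)
          }
        }
        P <- newP
        fit <- apply(P, 1, fitOf)
        ## elitism makes the best-so-far non-increasing
        h[gen] <- min(fit)
        if (gen > 1 && h[gen] > h[gen - 1]) h[gen] <- h[gen - 1]
      }
      b <- which.min(fit)
      list(history = cummin(h), fit = fit[b], bits = P[b, ])
    })
    history[[r]] <- restart$history
    if (restart$fit < bestFit) {
      bestFit <- restart$fit
      bestBits <- restart$bits
    }
  }
  if (is.null(bestBits)) stop("GA failed to find any feasible chromosome",
                              call. = FALSE)
  new("GAResult", selected = as.integer(sort(which(bestBits))),
      bestFitness = bestFit, fitnessHistory = history)
}
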
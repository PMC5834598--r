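#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' One centroided direct-infusion mass spectrum
#'
#' A single sample's peak list: paired, strictly increasing m/z values (Th)
#' and non-negative intensities, with a sample identifier and a two-level
#' class label ("NILM" or "SIL").
#'
#' @slot sampleId character(1) sample identifier.
#' @slot label character(1), "NILM" or "SIL".
#' @slot mz numeric vector of m/z values, strictly increasing.
#' @slot intensity numeric vector of intensities, same length as `mz`,
#'   all non-negative.
#'
#' @exportClass MassSpectrum
setClass("MassSpectrum",
  representation(
    sampleId = "character",
    label = "character",
    mz = "numeric",
    intensity = "numeric"
  )
)

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (length(object@label) != 1L ||
      !object@label %in% c("NILM", "SIL")) {
    msg <- c(msg, "label must be one of 'NILM', 'SIL'")
  }
  if (length(object@mz) != length(object@intensity)) {
    msg <- c(msg, "mz and intensity must have equal length")
  }
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0)) {
    msg <- c(msg, "mz must be strictly increasing")
  }
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg) > 0) msg else TRUE
})

#' Construct a MassSpectrum
#'
#' @param sampleId character(1) identifier.
#' @param label class label, "NILM" or "SIL".
#' @param mz strictly increasing numeric vector of m/z values (Th).
#' @param intensity non-negative intensities, same length as `mz`.
#' @return A [MassSpectrum-class] object.
#' @examples
#' massSpectrum("s1", "NILM", c(200.1, 350.2), c(10, 20))
#' @export
massSpectrum <- function(sampleId, label, mz, intensity) {
  new("MassSpectrum",
      sampleId = as.character(sampleId), label = as.character(label),
      mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' Configuration of a synthetic direct-infusion cohort
#'
#' Describes the statistical structure of a simulated two-class plasma
#' lipidomics cohort: cohort sizes, the m/z window, shared background
#' chemistry, class-differential marker peaks, per-sample mass jitter,
#' multiplicative intensity noise and a sub-threshold decoy noise floor.
#' The defaults emulate the study conditions this package targets:
#' 42 NILM and 34 SIL samples over m/z 200--1200 with five marker lipids.
#'
#' @slot nClassA count of NILM samples (default 42).
#' @slot nClassB count of SIL samples (default 34).
#' @slot mzRange numeric(2), m/z window in Th (default c(200, 1200)).
#' @slot nBackgroundPeaks count of shared background lipid peaks.
#' @slot markerTable data.frame with columns `mz` (Th), `upClass`
#'   ("NILM"/"SIL") and `effectSize` (fold-change > 0 of the up-class mean
#'   over the other class's mean).
#' @slot mzJitterPpm standard deviation (ppm) of the per-sample Gaussian
#'   perturbation of every peak position.
#' @slot intensityCv coefficient of variation of the multiplicative
#'   log-normal intensity noise.
#' @slot noiseFloor fraction of the maximum background mean intensity below
#'   which per-sample decoy peaks are drawn.
#' @slot nDecoyPeaks count of per-sample random low-intensity decoy peaks.
#' @slot markerBaseIntensity baseline mean intensity of a marker peak in its
#'   down-class (relative units).
#' @slot lowMzBias non-negative density weighting of background peak
#'   positions toward low m/z (0 = uniform).
#' @slot seed integer RNG seed; the cohort is fully reproducible from it.
#'
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nClassA = "numeric",
    nClassB = "numeric",
    mzRange = "numeric",
    nBackgroundPeaks = "numeric",
    markerTable = "data.frame",
    mzJitterPpm = "numeric",
    intensityCv = "numeric",
    noiseFloor = "numeric",
    nDecoyPeaks = "numeric",
    markerBaseIntensity = "numeric",
    lowMzBias = "numeric",
    seed = "numeric"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nClassA < 1) msg <- c(msg, "nClassA must be >= 1")
  if (object@nClassB < 1) msg <- c(msg, "nClassB must be >= 1")
  if (length(object@mzRange) != 2L || object@mzRange[1] >= object@mzRange[2]) {
    msg <- c(msg, "mzRange must satisfy lower < upper")
  }
  mt <- object@markerTable
  if (nrow(mt) > 0) {
    if (!all(c("mz", "upClass", "effectSize") %in% names(mt))) {
      msg <- c(msg, "markerTable must have columns mz, upClass, effectSize")
    } else {
      if (any(mt$effectSize <= 0)) msg <- c(msg, "effectSize must be > 0")
      if (!all(mt$upClass %in% c("NILM", "SIL"))) {
        msg <- c(msg, "markerTable upClass must be 'NILM' or 'SIL'")
      }
    }
  }
  if (object@mzJitterPpm < 0) msg <- c(msg, "mzJitterPpm must be >= 0")
  if (object@intensityCv < 0) msg <- c(msg, "intensityCv must be >= 0")
  if (object@noiseFloor < 0 || object@noiseFloor >= 1) {
    msg <- c(msg, "noiseFloor must be in [0, 1)")
  }
  if (object@lowMzBias < 0) msg <- c(msg, "lowMzBias must be >= 0")
  if (length(msg) > 0) msg else TRUE
})

#' Samples-by-features intensity matrix on a common m/z axis
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with one assay
#' `"intensity"` holding features (common-axis m/z bins) in rows and samples
#' in columns. `rowData` carries the merged m/z axis, `colData` the sample
#' identifiers and NILM/SIL labels, and two provenance flags in `metadata`
#' record whether the matrix has been row-normalised and ROI-compressed.
#' Use [intensityMatrix()] to obtain the samples-by-features orientation
#' that the splitters and classifiers consume.
#'
#' @exportClass LipidFeatureSet
setClass("LipidFeatureSet", contains = "SummarizedExperiment")

setValidity("LipidFeatureSet", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'intensity' is required")
  }
  mz <- rowData(object)$mz
  if (is.null(mz)) msg <- c(msg, "rowData must contain an 'mz' column")
  else if (length(mz) > 1L && any(diff(mz) <= 0)) {
    msg <- c(msg, "m/z axis must be strictly increasing")
  }
  cd <- colData(object)
  if (is.null(cd$label) || is.null(cd$sample_id)) {
    msg <- c(msg, "colData must contain 'sample_id' and 'label'")
  }
  fl <- metadata(object)$flags
  if (is.null(fl) || !all(c("normalized", "roiCompressed") %in% names(fl))) {
    msg <- c(msg, "metadata flags 'normalized' and 'roiCompressed' required")
  } else if (isTRUE(fl$normalized) && !isTRUE(fl$roiCompressed)) {
    ## after ROI compression the dropped columns carry away signal, so unit
    ## row norms are only checkable on the uncompressed matrix
    ss <- colSums(assay(object, "intensity")^2)
    if (any(abs(ss - 1) > 1e-10)) {
      msg <- c(msg, "normalized flag set but some sample has sum of squares != 1")
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' Record of a region-of-interest compression
#'
#' @slot keptIndices strictly increasing indices (into the pre-compression
#'   axis) of the retained columns.
#' @slot thresholdValue absolute intensity threshold actually applied.
#' @slot thresholdFraction fraction of the global maximum intensity the
#'   threshold was derived from (default 0.03).
#'
#' @exportClass RoiReport
setClass("RoiReport",
  representation(
    keptIndices = "integer",
    thresholdValue = "numeric",
    thresholdFraction = "numeric"
  )
)

setValidity("RoiReport", function(object) {
  msg <- character()
  if (length(object@keptIndices) > 1L && any(diff(object@keptIndices) <= 0)) {
    msg <- c(msg, "keptIndices must be strictly increasing")
  }
  if (object@thresholdFraction <= 0 || object@thresholdFraction >= 1) {
    msg <- c(msg, "thresholdFraction must be in (0, 1)")
  }
  if (length(msg) > 0) msg else TRUE
})

#' Training/validation/prediction partition of a cohort
#'
#' Pairwise-disjoint, exhaustive index sets produced by the Kennard-Stone
#' splitter. Indices refer to samples (columns) of the originating
#' [LipidFeatureSet-class].
#'
#' @slot train integer indices of the training set.
#' @slot validation integer indices of the validation set.
#' @slot prediction integer indices of the prediction (test) set.
#' @slot fractions numeric(3) nominal split fractions (default 0.70/0.15/0.15).
#'
#' @exportClass SplitIndices
setClass("SplitIndices",
  representation(
    train = "integer",
    validation = "integer",
    prediction = "integer",
    fractions = "numeric"
  )
)

setValidity("SplitIndices", function(object) {
  msg <- character()
  all_idx <- c(object@train, object@validation, object@prediction)
  if (anyDuplicated(all_idx)) msg <- c(msg, "index sets must be disjoint")
  n <- length(all_idx)
  if (!setequal(all_idx, seq_len(n))) {
    msg <- c(msg, "index sets must partition 1..n")
  }
  if (length(object@fractions) != 3L ||
      abs(sum(object@fractions) - 1) > 1e-9) {
    msg <- c(msg, "fractions must be length 3 and sum to 1")
  }
  if (length(msg) > 0) msg else TRUE
})

#' Fitted principal component model
#'
#' Column-mean-centred SVD of the training matrix. The sign convention fixes
#' each loading so that its largest-magnitude entry is positive.
#'
#' @slot center per-feature training means used for centring.
#' @slot loadings p x k matrix with orthonormal columns.
#' @slot explainedVarianceFraction length-k, non-increasing, each in [0, 1].
#' @slot k number of retained components (default 10).
#'
#' @exportClass PCAModel
setClass("PCAModel",
  representation(
    center = "numeric",
    loadings = "matrix",
    explainedVarianceFraction = "numeric",
    k = "integer"
  )
)

setValidity("PCAModel", function(object) {
  msg <- character()
  L <- object@loadings
  if (ncol(L) != object@k) msg <- c(msg, "loadings must have k columns")
  G <- crossprod(L)
  if (max(abs(G - diag(ncol(L)))) > 1e-8) {
    msg <- c(msg, "loadings must be orthonormal")
  }
  ev <- object@explainedVarianceFraction
  if (any(ev < 0) || any(ev > 1) || sum(ev) > 1 + 1e-8) {
    msg <- c(msg, "explained variance fractions must lie in [0,1], sum <= 1")
  }
  if (length(ev) > 1L && any(diff(ev) > 1e-12)) {
    msg <- c(msg, "explained variance fractions must be non-increasing")
  }
  if (length(msg) > 0) msg else TRUE
})

#' Genetic-algorithm settings for variable selection
#'
#' Defaults follow the published optimisation protocol: 40 generations of 80
#' chromosomes, crossover probability 0.60, per-bit mutation probability
#' 0.10, and three restarts from independent random initial populations.
#'
#' @slot nGenerations generations per restart (default 40).
#' @slot population chromosomes per generation, even (default 80).
#' @slot crossoverProb single-point crossover probability (default 0.60).
#' @slot mutationProb per-bit mutation probability (default 0.10).
#' @slot nRestarts independent restarts (default 3).
#' @slot initBitProb probability a bit is on in the initial population.
#' @slot maxVariables hard cap on selected variables; chromosomes above it
#'   receive infinite fitness.
#' @slot seed integer root seed; restart r uses `seed + r - 1`.
#'
#' @exportClass GAConfig
setClass("GAConfig",
  representation(
    nGenerations = "numeric",
    population = "numeric",
    crossoverProb = "numeric",
    mutationProb = "numeric",
    nRestarts = "numeric",
    initBitProb = "numeric",
    maxVariables = "numeric",
    seed = "numeric"
  )
)

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@nGenerations < 1) msg <- c(msg, "nGenerations must be >= 1")
  if (object@population < 2) msg <- c(msg, "population must be >= 2")
  if (object@population %% 2 != 0) msg <- c(msg, "population must be even")
  for (p in c("crossoverProb", "mutationProb", "initBitProb")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0, 1]"))
  }
  if (object@nRestarts < 1) msg <- c(msg, "nRestarts must be >= 1")
  if (object@maxVariables < 1) msg <- c(msg, "maxVariables must be >= 1")
  if (length(msg) > 0) msg else TRUE
})

#' Result of genetic-algorithm variable selection
#'
#' @slot selected strictly increasing indices of the selected variables.
#' @slot bestFitness best (lowest) average misclassification risk G found.
#' @slot fitnessHistory list, one numeric vector per restart, holding the
#'   best-so-far fitness at each generation (non-increasing under elitism).
#'
#' @exportClass GAResult
setClass("GAResult",
  representation(
    selected = "integer",
    bestFitness = "numeric",
    fitnessHistory = "list"
  )
)

setValidity("GAResult", function(object) {
  msg <- character()
  if (length(object@selected) > 1L && any(diff(object@selected) <= 0)) {
    msg <- c(msg, "selected indices must be strictly increasing")
  }
  if (object@bestFitness < 0) msg <- c(msg, "bestFitness must be >= 0")
  for (h in object@fitnessHistory) {
    if (length(h) > 1L && any(diff(h) > 1e-12)) {
      msg <- c(msg, "fitness history must be non-increasing within a restart")
      break
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' Per-class first and second moments of a training set
#'
#' Houses the class mean vectors, the pooled covariance, the per-class
#' covariances and the class priors consumed by the discriminant scores and
#' the GA fitness.
#'
#' @slot classes ordered class labels.
#' @slot means list of per-class mean vectors.
#' @slot pooled pooled (within-class) covariance matrix.
#' @slot perClass list of per-class covariance matrices.
#' @slot priors named class prior probabilities, summing to 1.
#'
#' @exportClass ClassStats
setClass("ClassStats",
  representation(
    classes = "character",
    means = "list",
    pooled = "matrix",
    perClass = "list",
    priors = "numeric"
  )
)

setValidity("ClassStats", function(object) {
  msg <- character()
  if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
  if (max(abs(object@pooled - t(object@pooled))) > 1e-8) {
    msg <- c(msg, "pooled covariance must be symmetric")
  }
  for (S in object@perClass) {
    if (max(abs(S - t(S))) > 1e-8) {
      msg <- c(msg, "per-class covariances must be symmetric")
      break
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' Linear or quadratic discriminant model
#'
#' @slot kind "LDA" (shared pooled covariance) or "QDA" (per-class
#'   covariances with a log-determinant term).
#' @slot stats the fitted [ClassStats-class].
#'
#' @exportClass DiscriminantModel
setClass("DiscriminantModel",
  representation(kind = "character", stats = "ClassStats")
)

setValidity("DiscriminantModel", function(object) {
  if (!object@kind %in% c("LDA", "QDA")) return("kind must be 'LDA' or 'QDA'")
  TRUE
})

#' Kernel specification for the support vector machine
#'
#' One of five kernels: linear x'z; quadratic (tau + x'z)^2; cubic
#' polynomial (tau + x'z)^3; radial basis function exp(-gamma ||x - z||^2);
#' multilayer perceptron tanh(k1 x'z + k2). Parameters are validated against
#' the kernel that needs them.
#'
#' @slot name one of "linear", "quadratic", "poly3", "rbf", "mlp".
#' @slot tau offset (>= 0) for the quadratic and cubic kernels.
#' @slot gamma width (> 0) of the RBF kernel.
#' @slot k1,k2 constants of the MLP (sigmoid) kernel.
#'
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(name = "character", tau = "numeric", gamma = "numeric",
                 k1 = "numeric", k2 = "numeric")
)

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (!object@name %in% c("linear", "quadratic", "poly3", "rbf", "mlp")) {
    msg <- c(msg, "unknown kernel name")
  }
  if (object@name %in% c("quadratic", "poly3")) {
    if (length(object@tau) != 1L || object@tau < 0) {
      msg <- c(msg, "tau must be a single value >= 0")
    }
  }
  if (object@name == "rbf") {
    ## NA gamma is allowed at construction: it is resolved to 1/nFeatures
    ## when the SVM is fitted
    if (length(object@gamma) != 1L ||
        (!is.na(object@gamma) && object@gamma <= 0)) {
      msg <- c(msg, "gamma must be a single value > 0")
    }
  }
  if (object@name == "mlp") {
    if (length(object@k1) != 1L || length(object@k2) != 1L) {
      msg <- c(msg, "k1 and k2 must be single values")
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' Fitted soft-margin support vector machine
#'
#' Dual solution of the two-class soft-margin problem. Only rows with
#' alpha > 1e-8 (the support vectors) are retained. The decision function is
#' f(z) = sum_i alpha_i y_i k(x_i, z) + b, with class sign(f) and SIL mapped
#' to +1.
#'
#' @slot supportVectors matrix of support-vector rows.
#' @slot alpha Lagrange multipliers of the support vectors, in (0, C].
#' @slot y signed labels (+1 / -1) of the support vectors.
#' @slot b bias.
#' @slot C box constraint.
#' @slot kernel the [KernelSpec-class] used.
#' @slot converged logical; FALSE when the optimiser hit its iteration cap
#'   (possible for the indefinite MLP kernel).
#'
#' @exportClass SvmModel
setClass("SvmModel",
  representation(
    supportVectors = "matrix",
    alpha = "numeric",
    y = "numeric",
    b = "numeric",
    cost = "numeric",
    kernel = "KernelSpec",
    converged = "logical"
  )
)

setValidity("SvmModel", function(object) {
  msg <- character()
  if (any(object@alpha < 0) || any(object@alpha > object@cost + 1e-8)) {
    msg <- c(msg, "alphas must satisfy 0 <= alpha <= C")
  }
  if (!all(object@y %in% c(-1, 1))) msg <- c(msg, "y must be +/- 1")
  if (length(msg) > 0) msg else TRUE
})
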
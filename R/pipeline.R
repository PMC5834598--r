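## End-to-end orchestration: simulate/read -> common axis -> normalise ->
## ROI -> split -> reduce -> train -> evaluate -> annotate, with a
## line-delimited run log and one root seed feeding every random stage.

#' Default classifier grid
#'
#' The eleven model configurations evaluated by default: PCA and GA paired
#' with LDA and QDA, KNN on the full compressed spectra, PCA paired with
#' all five SVM kernels, and SVM-RBF alone on the full compressed spectra.
#'
#' @return data.frame with columns `features` ("pca", "ga", "none"),
#'   `classifier` ("lda", "qda", "svm", "knn") and `kernel` (SVM kernel
#'   name or NA).
#' @export
defaultModelGrid <- function() {
  data.frame(
    features = c("pca", "ga", "pca", "ga", "none",
                  "pca", "pca", "pca", "pca", "pca", "none"),
    classifier = c("lda", "lda", "qda", "qda", "knn",
                    "svm", "svm", "svm", "svm", "svm", "svm"),
    kernel = c(NA, NA, NA, NA, NA,
                "linear", "quadratic", "poly3", "rbf", "mlp", "rbf"),
    stringsAsFactors = FALSE
  )
}

#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: a synthetic
#' [CohortConfig-class] or a directory of peak lists with a manifest.
#'
#' @param synthetic a [CohortConfig-class], or NULL.
#' @param peaklistDir directory readable by [readPeakLists()], or NULL.
#' @param mergeTolPpm common-axis merge tolerance (ppm).
#' @param roiFraction ROI threshold fraction of the maximum intensity.
#' @param fractions train/validation/prediction fractions, summing to 1.
#' @param stratified stratify the Kennard-Stone split by class.
#' @param pcaK PCA component count.
#' @param ga a [GAConfig-class] used when the grid contains GA models.
#' @param grid model grid as in [defaultModelGrid()].
#' @param svmC SVM box constraint.
#' @param knnGrid candidate odd k values for KNN.
#' @param annotationTopN discriminant features to annotate.
#' @param annotationTolPpm reference-match tolerance (ppm).
#' @param seed root seed; the synthetic generator uses it directly and the
#'   GA uses `seed + 1000`.
#' @return list of class `"lipoclassRunConfig"`.
#' @export
runConfig <- function(synthetic = cohortConfig(), peaklistDir = NULL,
                      mergeTolPpm = 5, roiFraction = 0.03,
                      fractions = c(0.70, 0.15, 0.15), stratified = TRUE,
                      pcaK = 10, ga = gaConfig(), grid = defaultModelGrid(),
                      svmC = 1, knnGrid = c(1, 3, 5, 7, 9),
                      annotationTopN = 5, annotationTolPpm = 10,
                      seed = 1) {
  if (is.null(synthetic) == is.null(peaklistDir)) {
    stop("exactly one input source (synthetic or peaklistDir) is required",
         call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  if (!is.null(synthetic)) {
    synthetic@seed <- seed
    ga@seed <- seed + 1000
  }
  structure(list(
    synthetic = synthetic, peaklistDir = peaklistDir,
    mergeTolPpm = mergeTolPpm, roiFraction = roiFraction,
    fractions = fractions, stratified = stratified, pcaK = pcaK, ga = ga,
    grid = grid, svmC = svmC, knnGrid = knnGrid,
    annotationTopN = annotationTopN, annotationTolPpm = annotationTolPpm,
    seed = seed
  ), class = "lipoclassRunConfig")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Scalar fields of [runConfig()] may be set in the file; `synthetic` and
#' `ga` accept nested key-value blocks passed to [cohortConfig()] and
#' [gaConfig()]. A `peaklist_dir` key switches the input source to disk.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return list of class `"lipoclassRunConfig"`.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  args <- list()
  if (!is.null(raw$peaklist_dir)) {
    args$peaklistDir <- raw$peaklist_dir
    args$synthetic <- NULL
  } else if (!is.null(raw$synthetic)) {
    args$synthetic <- do.call(cohortConfig, raw$synthetic)
  }
  if (!is.null(raw$ga)) args$ga <- do.call(gaConfig, raw$ga)
  for (f in c("mergeTolPpm", "roiFraction", "fractions", "stratified",
              "pcaK", "svmC", "knnGrid", "annotationTopN",
              "annotationTolPpm", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(runConfig, args)
}

## Serialise a fitted model to a plain-list JSON schema.
.modelToList <- function(fit) {
  if (is(fit, "DiscriminantModel")) {
    st <- fit@stats
    list(type = fit@kind, classes = st@classes,
         means = lapply(st@means, as.numeric),
         pooled_covariance = st@pooled,
         per_class_covariance = st@perClass, priors = as.list(st@priors))
  } else if (is(fit, "SvmModel")) {
    list(type = "SVM", kernel = fit@kernel@name, tau = fit@kernel@tau,
         gamma = fit@kernel@gamma, k1 = fit@kernel@k1, k2 = fit@kernel@k2,
         C = fit@cost, b = fit@b, alpha = fit@alpha, y = fit@y,
         support_vectors = fit@supportVectors, converged = fit@converged)
  } else {
    fit  # already a plain list (e.g. KNN)
  }
}

#' Run the full classification pipeline
#'
#' Executes the fixed stage order: input (simulate or read) -> common m/z
#' axis -> row normalisation -> ROI compression -> Kennard-Stone split ->
#' feature reduction (PCA scores and/or GA variable selection, as the model
#' grid requires) -> classifier training -> evaluation on the held-out
#' prediction set -> annotation of the top discriminant features. Any
#' stage failure halts the run with the stage name. All artifacts
#' (compressed feature matrix, ROI report, split, serialised models,
#' evaluation report, annotation table, run log) are written to
#' `outputDir`; repeated runs with the same configuration produce
#' byte-identical reports.
#'
#' Feature handling per grid row: `"pca"` trains on PCA scores of the
#' training set; `"ga"` trains on the GA-selected variables (the GA is run
#' once per pipeline and shared across GA models, since its fitness does
#' not depend on the downstream classifier); `"none"` trains on the full
#' compressed spectra. ROC scores are the raw pre-threshold decision
#' values (discriminant score differences, SVM f before sign, KNN vote
#' fraction).
#'
#' @param config list from [runConfig()] or [readRunConfig()].
#' @param outputDir artifact directory, created if needed.
#' @return Invisibly, a list with the feature set, split, report,
#'   annotation and per-model predictions.
#' @export
runPipeline <- function(config, outputDir = tempfile("lipoclass_run_")) {
  stopifnot(inherits(config, "lipoclassRunConfig"))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outputDir, "run_log.jsonl")
  if (file.exists(logPath)) file.remove(logPath)
  logRec <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = logPath, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logRec(name, error = conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  spectra <- stage("input", {
    if (!is.null(config$synthetic)) {
      logRec("input", source = "synthetic", seed = config$synthetic@seed)
      generateCohort(config$synthetic)
    } else {
      logRec("input", source = "peaklists", dir = config$peaklistDir)
      readPeakLists(config$peaklistDir)
    }
  })

  fm <- stage("common_axis",
              buildCommonAxis(spectra, config$mergeTolPpm))
  logRec("common_axis", n_samples = ncol(fm), n_features = nrow(fm),
         merge_tol_ppm = config$mergeTolPpm)

  fm <- stage("normalize", normalizeRows(fm))
  roi <- stage("roi", roiSelect(fm, config$roiFraction))
  fm <- roi$fm
  logRec("roi", kept = length(roi$report@keptIndices),
         threshold = roi$report@thresholdValue)
  writeFeatureMatrix(fm, file.path(outputDir, "feature_matrix.csv"))
  writeRoiReport(roi$report, file.path(outputDir, "roi_report.csv"))

  split <- stage("split",
                 splitKennardStone(fm, stratified = config$stratified,
                                   fractions = config$fractions))
  logRec("split", train = length(split@train),
         validation = length(split@validation),
         prediction = length(split@prediction),
         stratified = config$stratified)
  writeSplit(split, fm, file.path(outputDir, "split.csv"))

  X <- intensityMatrix(fm)
  labs <- classLabels(fm)
  itr <- split@train
  iva <- split@validation
  ipr <- split@prediction

  grid <- config$grid
  needPca <- any(grid$features == "pca")
  needGa <- any(grid$features == "ga")

  pca <- NULL
  if (needPca) {
    pca <- stage("reduce_pca", pcaFit(X[itr, , drop = FALSE], config$pcaK))
    logRec("reduce_pca", k = pca@k,
           explained = sum(pca@explainedVarianceFraction))
  }
  gaRes <- NULL
  if (needGa) {
    gaRes <- stage("reduce_ga",
                   gaSelect(X[itr, , drop = FALSE], labs[itr],
                            X[iva, , drop = FALSE], labs[iva],
                            config$ga))
    logRec("reduce_ga", n_selected = length(gaRes@selected),
           best_fitness = gaRes@bestFitness, seed = config$ga@seed)
    utils::write.csv(
      data.frame(index = gaRes@selected, mz = mzAxis(fm)[gaRes@selected]),
      file.path(outputDir, "ga_selected.csv"), row.names = FALSE,
      quote = FALSE)
  }

  featView <- function(mode, idx) {
    switch(mode,
      pca = pcaScores(pca, X[idx, , drop = FALSE]),
      ga = X[idx, gaRes@selected, drop = FALSE],
      none = X[idx, , drop = FALSE])
  }

  predictions <- list()
  models <- list()
  for (g in seq_len(nrow(grid))) {
    feat <- grid$features[g]
    clf <- grid$classifier[g]
    kern <- grid$kernel[g]
    nm <- paste0(
      switch(feat, pca = "PCA-", ga = "GA-", none = ""),
      switch(clf, lda = "LDA", qda = "QDA", knn = "KNN",
             svm = paste0("SVM-", switch(kern, linear = "L",
                                         quadratic = "Q", poly3 = "P",
                                         rbf = "RBF", mlp = "MLP")))
    )
    res <- stage(paste0("train_", nm), {
      Xtr <- featView(feat, itr)
      Xpr <- featView(feat, ipr)
      if (clf == "lda" || clf == "qda") {
        fit <- discriminantFit(Xtr, labs[itr], toupper(clf))
        pr <- discriminantPredict(fit, Xpr)
        list(fit = fit, class = pr$class, score = pr$score)
      } else if (clf == "svm") {
        spec <- kernelSpec(kern)
        fit <- suppressWarnings(
          svmTrain(Xtr, labs[itr], spec, C = config$svmC))
        pr <- svmDecision(fit, Xpr)
        list(fit = fit, class = pr$class, score = pr$score)
      } else {  # knn on the full compressed spectra
        Xva <- featView(feat, iva)
        k <- knnSelectK(Xtr, labs[itr], Xva, labs[iva], config$knnGrid)
        pr <- knnClassify(Xtr, labs[itr], Xpr, k = k)
        list(fit = list(type = "KNN", k = k), class = pr$class,
             score = pr$score)
      }
    })
    predictions[[nm]] <- list(class = res$class, score = res$score)
    models[[nm]] <- res$fit
    logRec(paste0("train_", nm), features = feat, classifier = clf,
           kernel = if (is.na(kern)) NULL else kern)
  }

  report <- stage("evaluate", buildReport(predictions, labs[ipr]))
  utils::write.csv(report, file.path(outputDir, "report.csv"),
                   row.names = FALSE, quote = FALSE)

  annotation <- stage("annotate", {
    d <- differenceSpectrum(fm)
    ranked <- rankDiscriminantFeatures(d, config$annotationTopN)
    matchReference(ranked, tolPpm = config$annotationTolPpm)
  })
  utils::write.csv(annotation, file.path(outputDir, "annotation.csv"),
                   row.names = FALSE, quote = FALSE)

  jsonlite::write_json(lapply(models, .modelToList),
                       file.path(outputDir, "models.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  logRec("done", output_dir = outputDir, seed = config$seed)

  invisible(list(featureSet = fm, roiReport = roi$report, split = split,
                 pca = pca, ga = gaRes, report = report,
                 annotation = annotation, predictions = predictions,
                 outputDir = outputDir))
}
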
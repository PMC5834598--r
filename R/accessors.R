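## Accessors and show methods for the core S4 containers.

#' @name lipoclass-accessors
#' @title Accessors for lipoclass containers
#' @description Accessor generics for the package's S4 containers:
#'   the common m/z axis, the samples-by-features intensity matrix, sample
#'   identifiers, class labels and the preprocessing provenance flags.
#' @param object A package object ([MassSpectrum-class] or
#'   [LipidFeatureSet-class]).
#' @return `mzAxis()` and `classLabels()` return numeric and character
#'   vectors; `intensityMatrix()` returns a samples x features matrix;
#'   `sampleIds()` a character vector; `isNormalized()` /
#'   `isRoiCompressed()` a logical(1).
NULL

#' @rdname lipoclass-accessors
#' @export
setGeneric("mzAxis", function(object) standardGeneric("mzAxis"))

#' @rdname lipoclass-accessors
#' @export
setGeneric("intensityMatrix",
           function(object) standardGeneric("intensityMatrix"))

#' @rdname lipoclass-accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname lipoclass-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname lipoclass-accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname lipoclass-accessors
#' @export
setGeneric("isRoiCompressed",
           function(object) standardGeneric("isRoiCompressed"))

#' @rdname lipoclass-accessors
#' @export
setMethod("mzAxis", "MassSpectrum", function(object) object@mz)

#' @rdname lipoclass-accessors
#' @export
setMethod("classLabels", "MassSpectrum", function(object) object@label)

#' @rdname lipoclass-accessors
#' @export
setMethod("sampleIds", "MassSpectrum", function(object) object@sampleId)

#' @rdname lipoclass-accessors
#' @export
setMethod("mzAxis", "LipidFeatureSet", function(object) {
  as.numeric(rowData(object)$mz)
})

#' @rdname lipoclass-accessors
#' @export
setMethod("intensityMatrix", "LipidFeatureSet", function(object) {
  t(assay(object, "intensity"))
})

#' @rdname lipoclass-accessors
#' @export
setMethod("classLabels", "LipidFeatureSet", function(object) {
  as.character(colData(object)$label)
})

#' @rdname lipoclass-accessors
#' @export
setMethod("sampleIds", "LipidFeatureSet", function(object) {
  as.character(colData(object)$sample_id)
})

#' @rdname lipoclass-accessors
#' @export
setMethod("isNormalized", "LipidFeatureSet", function(object) {
  isTRUE(metadata(object)$flags$normalized)
})

#' @rdname lipoclass-accessors
#' @export
setMethod("isRoiCompressed", "LipidFeatureSet", function(object) {
  isTRUE(metadata(object)$flags$roiCompressed)
})

#' Split accessors
#'
#' @param object A [SplitIndices-class].
#' @return Integer sample indices.
#' @name split-accessors
NULL

#' @rdname split-accessors
#' @export
trainIndices <- function(object) object@train

#' @rdname split-accessors
#' @export
validationIndices <- function(object) object@validation

#' @rdname split-accessors
#' @export
predictionIndices <- function(object) object@prediction

#' @describeIn gaSelect Selected variable indices of a [GAResult-class].
#' @export
selectedVariables <- function(object) object@selected

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum '", object@sampleId, "' (", object@label, "): ",
      length(object@mz), " peaks, m/z ",
      if (length(object@mz)) {
        paste0(format(min(object@mz), digits = 6), "-",
               format(max(object@mz), digits = 6))
      } else "-", "\n", sep = "")
})

setMethod("show", "LipidFeatureSet", function(object) {
  cat("LipidFeatureSet: ", ncol(object), " samples x ", nrow(object),
      " m/z features\n", sep = "")
  tab <- table(classLabels(object))
  cat("  classes: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  normalized: ", isNormalized(object),
      "; ROI-compressed: ", isRoiCompressed(object), "\n", sep = "")
})

setMethod("show", "SplitIndices", function(object) {
  cat("SplitIndices: train=", length(object@train),
      " validation=", length(object@validation),
      " prediction=", length(object@prediction), "\n", sep = "")
})

setMethod("show", "GAResult", function(object) {
  cat("GAResult: ", length(object@selected), " variables selected, best G = ",
      format(object@bestFitness, digits = 4), " over ",
      length(object@fitnessHistory), " restart(s)\n", sep = "")
})

setMethod("show", "SvmModel", function(object) {
  cat("SvmModel (", object@kernel@name, " kernel): ",
      length(object@alpha), " support vectors, C = ", object@cost,
      if (!object@converged) " [not converged]" else "", "\n", sep = "")
})

setMethod("show", "RoiReport", function(object) {
  cat("RoiReport: ", length(object@keptIndices), " columns kept at threshold ",
      format(object@thresholdValue, digits = 4), " (",
      object@thresholdFraction * 100, "% of global maximum)\n", sep = "")
})
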
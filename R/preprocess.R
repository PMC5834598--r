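## Peak-list I/O, common m/z axis construction, normalisation and ROI
## compression.

#' Read per-sample peak-list CSVs via a manifest
#'
#' Inverse of [writePeakLists()]: reads `manifest.csv`
#' (`sample_id,label,filename`, with header) and one headerless
#' `mz,intensity` CSV per sample.
#'
#' @param directory directory containing the manifest and the peak lists.
#' @param manifest manifest filename (default `"manifest.csv"`).
#' @return list of [MassSpectrum-class].
#' @export
readPeakLists <- function(directory, manifest = "manifest.csv") {
  mpath <- file.path(directory, manifest)
  if (!file.exists(mpath)) stop("manifest not found: ", mpath, call. = FALSE)
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.csv(file.path(directory, man$filename[i]),
                          header = FALSE, col.names = c("mz", "intensity"))
    massSpectrum(man$sample_id[i], man$label[i], df$mz, df$intensity)
  })
}

## Agglomerative single-linkage merge of all observed m/z values: sorted
## values are split wherever the gap to the previous value exceeds the
## tolerance; each cluster becomes one column at the intensity-weighted
## mean position. Sequential by nature but cheap: one pass over the sorted
## union.
.mergeAxis <- function(mz, intensity, tolPpm) {
  ord <- order(mz)
  mzs <- mz[ord]
  gapPpm <- c(Inf, diff(mzs) / mzs[-length(mzs)] * 1e6)
  cluster <- cumsum(gapPpm > tolPpm)
  list(order = ord, cluster = cluster)
}

#' Build the common m/z axis and assemble the feature matrix
#'
#' Direct-infusion samples each carry their own mass axis. This routine
#' forms the union of all observed m/z values, agglomeratively merges
#' values closer than `mergeTolPpm` (single linkage on the sorted union;
#' merged position = intensity-weighted mean of the merged values), and
#' places each sample's intensities at their merged columns, zero
#' elsewhere. Values from the same sample that fall in one merged column
#' are summed. The result is independent of the order of the input spectra
#' up to row (sample) ordering.
#'
#' @param spectra non-empty list of [MassSpectrum-class].
#' @param mergeTolPpm merge tolerance in ppm (default 5, consistent with
#'   sub-2-ppm Orbitrap mass accuracy).
#' @return A [LipidFeatureSet-class] with neither provenance flag set.
#' @examples
#' a <- massSpectrum("a", "NILM", c(400.0000), 10)
#' b <- massSpectrum("b", "SIL",  c(400.0010), 20)
#' nrow(buildCommonAxis(list(a, b), mergeTolPpm = 5))  # 1 merged column
#' nrow(buildCommonAxis(list(a, b), mergeTolPpm = 1))  # 2 columns
#' @export
buildCommonAxis <- function(spectra, mergeTolPpm = 5) {
  if (length(spectra) == 0) stop("empty spectrum list", call. = FALSE)
  stopifnot(mergeTolPpm >= 0)
  for (sp in spectra) stopifnot(is(sp, "MassSpectrum"))

  nPeaks <- vapply(spectra, function(sp) length(sp@mz), integer(1))
  allMz <- unlist(lapply(spectra, slot, "mz"))
  allInt <- unlist(lapply(spectra, slot, "intensity"))
  sampleIdx <- rep(seq_along(spectra), nPeaks)

  m <- .mergeAxis(allMz, allInt, mergeTolPpm)
  mzs <- allMz[m$order]
  ints <- allInt[m$order]
  sIdx <- sampleIdx[m$order]
  k <- max(m$cluster)

  ## merged position: intensity-weighted mean (plain mean if all-zero weight)
  wsum <- as.numeric(rowsum(ints, m$cluster))
  wpos <- as.numeric(rowsum(ints * mzs, m$cluster))
  cnt <- as.numeric(rowsum(rep(1, length(mzs)), m$cluster))
  psum <- as.numeric(rowsum(mzs, m$cluster))
  axis <- ifelse(wsum > 0, wpos / wsum, psum / cnt)

  n <- length(spectra)
  X <- matrix(0, nrow = k, ncol = n)  # features x samples
  key <- (sIdx - 1) * k + m$cluster
  acc <- rowsum(ints, key)
  ukey <- as.numeric(rownames(acc))
  X[cbind(((ukey - 1) %% k) + 1, ((ukey - 1) %/% k) + 1)] <- as.numeric(acc)

  se <- SummarizedExperiment(
    assays = list(intensity = X),
    rowData = DataFrame(mz = axis),
    colData = DataFrame(
      sample_id = vapply(spectra, slot, character(1), "sampleId"),
      label = vapply(spectra, slot, character(1), "label")
    ),
    metadata = list(flags = list(normalized = FALSE, roiCompressed = FALSE),
                    mergeTolPpm = mergeTolPpm)
  )
  out <- new("LipidFeatureSet", se)
  validObject(out)
  out
}

#' Normalise each sample to unit sum of squares
#'
#' Divides each sample's intensity vector by its Euclidean norm so the sum
#' of squares of every row of the samples-by-features matrix equals 1.
#' Idempotent; refuses all-zero samples.
#'
#' @param fm A [LipidFeatureSet-class].
#' @return The normalised [LipidFeatureSet-class] with the `normalized`
#'   flag set.
#' @export
normalizeRows <- function(fm) {
  stopifnot(is(fm, "LipidFeatureSet"))
  X <- assay(fm, "intensity")
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) {
    stop("cannot normalize all-zero sample(s): ",
         paste(sampleIds(fm)[nrm == 0], collapse = ", "), call. = FALSE)
  }
  SummarizedExperiment::assay(fm, "intensity") <-
    sweep(X, 2, nrm, "/")
  fl <- metadata(fm)$flags
  fl$normalized <- TRUE
  metadata(fm)$flags <- fl
  validObject(fm)
  fm
}

#' Region-of-interest compression at a fraction of the maximum intensity
#'
#' Keeps exactly the m/z columns in which at least one sample's intensity
#' is strictly greater than `thresholdFraction` times the global maximum of
#' the normalised matrix (3% by default). Columns exactly at the threshold
#' are dropped. Column order is preserved. The matrix must already be
#' normalised: the published workflow normalises first and compresses
#' second, and this function refuses the reversed order unless
#' `force = TRUE`.
#'
#' @param fm a normalised [LipidFeatureSet-class].
#' @param thresholdFraction fraction of the maximum intensity, in (0, 1)
#'   (default 0.03).
#' @param perSample if TRUE, threshold each sample against its own maximum
#'   instead of the single global maximum.
#' @param force bypass the normalised-first ordering guard.
#' @return list with elements `fm` (the compressed [LipidFeatureSet-class],
#'   `roiCompressed` flag set) and `report` (a [RoiReport-class]).
#' @export
roiSelect <- function(fm, thresholdFraction = 0.03, perSample = FALSE,
                      force = FALSE) {
  stopifnot(is(fm, "LipidFeatureSet"))
  if (thresholdFraction <= 0 || thresholdFraction >= 1) {
    stop("thresholdFraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (!isNormalized(fm) && !force) {
    stop("ROI compression requires a normalised matrix (normalise first, ",
         "then compress); use force = TRUE to override", call. = FALSE)
  }
  X <- assay(fm, "intensity")  # features x samples
  if (perSample) {
    thr <- thresholdFraction * apply(X, 2, max)
    keep <- rowSums(sweep(X, 2, thr, ">")) > 0
    thrValue <- thresholdFraction * max(X)
  } else {
    thrValue <- thresholdFraction * max(X)
    keep <- apply(X, 1, max) > thrValue
  }
  kept <- which(keep)
  out <- fm[kept, ]
  fl <- metadata(out)$flags
  fl$roiCompressed <- TRUE
  metadata(out)$flags <- fl
  report <- new("RoiReport", keptIndices = as.integer(kept),
                thresholdValue = thrValue,
                thresholdFraction = thresholdFraction)
  validObject(out)
  list(fm = out, report = report)
}

#' Difference between the NILM and SIL mean spectra
#'
#' Per-column difference mean(NILM) - mean(SIL) of a normalised,
#' ROI-compressed two-class matrix. A negative entry means that m/z feature
#' is more intense in the SIL class; swapping the class labels negates the
#' vector exactly.
#'
#' @param fm a normalised, ROI-compressed two-class
#'   [LipidFeatureSet-class].
#' @return data.frame with columns `mz` and `difference`.
#' @export
differenceSpectrum <- function(fm) {
  stopifnot(is(fm, "LipidFeatureSet"))
  if (!isNormalized(fm) || !isRoiCompressed(fm)) {
    stop("difference spectrum requires a normalised, ROI-compressed matrix",
         call. = FALSE)
  }
  labs <- classLabels(fm)
  lev <- unique(labs)
  if (length(lev) != 2L) {
    stop("exactly two class labels required, found ", length(lev),
         call. = FALSE)
  }
  assertLabels(labs)
  X <- assay(fm, "intensity")
  d <- rowMeans(X[, labs == "NILM", drop = FALSE]) -
       rowMeans(X[, labs == "SIL", drop = FALSE])
  data.frame(mz = mzAxis(fm), difference = as.numeric(d))
}

#' Write a feature matrix (and optional ROI report) to CSV
#'
#' One row per sample: `sample_id`, `label`, then one column per m/z value
#' of the common axis.
#'
#' @param fm A [LipidFeatureSet-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeFeatureMatrix <- function(fm, path) {
  X <- intensityMatrix(fm)
  colnames(X) <- format(mzAxis(fm), digits = 10, trim = TRUE)
  df <- data.frame(sample_id = sampleIds(fm), label = classLabels(fm),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param report A [RoiReport-class].
#' @export
writeRoiReport <- function(report, path) {
  df <- data.frame(kept_index = report@keptIndices,
                   threshold_value = report@thresholdValue,
                   threshold_fraction = report@thresholdFraction)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
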
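## Synthetic direct-infusion ESI cohort generator.
##
## Every downstream stage of the pipeline is exercised on cohorts produced
## here: centroided stick spectra on per-sample mass axes, shared background
## chemistry, class-differential marker peaks, and a sub-threshold decoy
## noise floor that the ROI compression is expected to remove.

#' Default class-differential marker peaks
#'
#' Five marker lipids: Tetranor-PGFM (m/z 331.177) and a hydroperoxide
#' fatty-acid derivative (m/z 397.258) elevated in the SIL class; a
#' prostaglandin (m/z 369.227), a serine glycerophospholipid (m/z 680.450)
#' and a sulfatide sphingolipid (m/z 780.526) elevated in the NILM class.
#'
#' @param effectSize fold-change of each marker's mean intensity in its
#'   up-class relative to the other class (default 5).
#' @return data.frame with columns `mz`, `upClass`, `effectSize`.
#' @examples
#' defaultMarkerTable()
#' @export
defaultMarkerTable <- function(effectSize = 5) {
  data.frame(
    mz = c(331.177, 369.227, 397.258, 680.450, 780.526),
    upClass = c("SIL", "NILM", "SIL", "NILM", "NILM"),
    effectSize = effectSize,
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic cohort
#'
#' Builds a [CohortConfig-class]. Defaults emulate the target study design:
#' 42 NILM + 34 SIL samples over m/z 200--1200, five marker peaks at
#' fold-change 5, 2 ppm per-sample mass jitter (Orbitrap-like accuracy),
#' 30% multiplicative intensity CV, 300 shared background peaks with
#' log-uniform (heavy-tailed) mean intensities, and 200 per-sample decoy
#' peaks under a 1% noise floor.
#'
#' @param nClassA,nClassB NILM and SIL sample counts.
#' @param mzRange m/z window in Th.
#' @param nBackgroundPeaks shared background peak count.
#' @param markerTable data.frame of marker peaks (see [defaultMarkerTable()]).
#' @param mzJitterPpm per-sample Gaussian position jitter, ppm sd.
#' @param intensityCv coefficient of variation of log-normal intensity noise.
#' @param noiseFloor decoy intensity ceiling, as a fraction of the largest
#'   background mean intensity.
#' @param nDecoyPeaks per-sample decoy peak count.
#' @param markerBaseIntensity marker mean intensity in its down-class.
#' @param lowMzBias >= 0; larger values concentrate background peaks at low
#'   m/z (0 = uniform positions).
#' @param seed integer RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cohortConfig(seed = 7)
#' @export
cohortConfig <- function(nClassA = 42, nClassB = 34,
                         mzRange = c(200, 1200),
                         nBackgroundPeaks = 300,
                         markerTable = defaultMarkerTable(),
                         mzJitterPpm = 2,
                         intensityCv = 0.3,
                         noiseFloor = 0.01,
                         nDecoyPeaks = 200,
                         markerBaseIntensity = 200,
                         lowMzBias = 0,
                         seed = 1) {
  cfg <- try(new("CohortConfig",
    nClassA = nClassA, nClassB = nClassB, mzRange = as.numeric(mzRange),
    nBackgroundPeaks = nBackgroundPeaks, markerTable = markerTable,
    mzJitterPpm = mzJitterPpm, intensityCv = intensityCv,
    noiseFloor = noiseFloor, nDecoyPeaks = nDecoyPeaks,
    markerBaseIntensity = markerBaseIntensity, lowMzBias = lowMzBias,
    seed = seed), silent = TRUE)
  if (inherits(cfg, "try-error")) {
    stop("invalid cohort configuration: ", attr(cfg, "condition")$message,
         call. = FALSE)
  }
  cfg
}

## Draw peak positions, optionally biased toward low m/z with density
## proportional to (1 + bias * (1 - u))  on the unit interval.
.drawPositions <- function(n, range, bias) {
  u <- stats::runif(n)
  if (bias > 0) {
    ## inverse-CDF of the linearly decreasing density 1 + bias * (1 - u)
    a <- 1 + bias
    u <- (a - sqrt(a^2 - bias * (2 + bias) * u)) / bias
    u <- pmin(pmax(u, 0), 1)
  }
  range[1] + u * diff(range)
}

#' Generate a synthetic two-class cohort of centroid spectra
#'
#' Draws the shared background chemistry once per cohort (positions uniform
#' or low-m/z-weighted, mean intensities log-uniform over three decades so a
#' few peaks dominate), then simulates each sample independently: every peak
#' position is perturbed by Gaussian ppm jitter so no two samples share a
#' mass axis; background and marker intensities vary log-normally around
#' class-conditional means (a marker's mean in its up-class equals
#' `effectSize` times its mean in the other class); and low-intensity decoy
#' peaks at per-sample random positions form a noise floor below the
#' eventual ROI threshold. The cohort is bit-reproducible from the seed and
#' the caller's RNG stream is left untouched.
#'
#' @param config A [CohortConfig-class].
#' @return List of [MassSpectrum-class], NILM samples first.
#' @examples
#' sp <- generateCohort(cohortConfig(nClassA = 3, nClassB = 2,
#'                                   nBackgroundPeaks = 20, nDecoyPeaks = 5))
#' length(sp)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, {
    nA <- as.integer(config@nClassA)
    nB <- as.integer(config@nClassB)
    rng <- config@mzRange
    nbg <- as.integer(config@nBackgroundPeaks)
    mt <- config@markerTable

    bgMz <- sort(.drawPositions(nbg, rng, config@lowMzBias))
    ## heavy-tailed background: log-uniform means over 3 decades
    bgMean <- 10^stats::runif(nbg, 0, 3)
    maxScale <- max(bgMean, 1)

    sigma <- sqrt(log(1 + config@intensityCv^2))
    labels <- c(rep("NILM", nA), rep("SIL", nB))
    ids <- sprintf("S%03d", seq_along(labels))

    lapply(seq_along(labels), function(i) {
      lab <- labels[i]
      markerMean <- config@markerBaseIntensity *
        ifelse(mt$upClass == lab, mt$effectSize, 1)
      mz0 <- c(bgMz, mt$mz)
      mean0 <- c(bgMean, markerMean)
      ## multiplicative log-normal noise with unit arithmetic mean
      inten <- mean0 * stats::rlnorm(length(mean0),
                                     meanlog = -sigma^2 / 2, sdlog = sigma)
      ## per-sample decoy noise floor
      nd <- as.integer(config@nDecoyPeaks)
      if (nd > 0) {
        mz0 <- c(mz0, .drawPositions(nd, rng, config@lowMzBias))
        inten <- c(inten,
                   stats::runif(nd, 0, config@noiseFloor * maxScale))
      }
      ## per-sample mass-axis jitter (ppm)
      mz <- mz0 * (1 + stats::rnorm(length(mz0)) * config@mzJitterPpm * 1e-6)
      mz <- pmin(pmax(mz, rng[1]), rng[2])
      ord <- order(mz)
      mz <- mz[ord]
      inten <- inten[ord]
      ## jitter makes exact ties measure-zero, but boundary clamping can
      ## create them; nudge duplicates apart by an epsilon ulp-scale step
      d <- which(diff(mz) <= 0)
      while (length(d) > 0) {
        mz[d + 1L] <- mz[d] + mz[d] * 1e-12
        d <- which(diff(mz) <= 0)
      }
      massSpectrum(ids[i], lab, mz, inten)
    })
  })
}

#' Write a cohort as per-sample peak-list CSVs with a manifest
#'
#' Writes one headerless two-column CSV (`mz,intensity`) per sample and a
#' `manifest.csv` (header `sample_id,label,filename`) into `directory`.
#' Values are written with enough digits to round-trip through
#' [readPeakLists()] to at least 12 significant digits.
#'
#' @param spectra list of [MassSpectrum-class].
#' @param directory output directory, created if needed.
#' @return Invisibly, the manifest data.frame.
#' @export
writePeakLists <- function(spectra, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  rows <- lapply(spectra, function(sp) {
    stopifnot(is(sp, "MassSpectrum"))
    fn <- paste0(sp@sampleId, ".csv")
    df <- data.frame(mz = sp@mz, intensity = sp@intensity)
    utils::write.table(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       file.path(directory, fn),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    data.frame(sample_id = sp@sampleId, label = sp@label, filename = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(), label = character(),
               filename = character(), stringsAsFactors = FALSE)
  }
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
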
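## Annotation of discriminant m/z features against a packaged lipid
## reference table.

## Monoisotopic masses of the most abundant isotopes (IUPAC/CODATA values),
## user-extensible through the `extra` argument of formulaMass().
.monoisotopicMasses <- c(
  C = 12.0000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069,
  Na = 22.98976928,
  K = 38.96370649,
  Cl = 34.96885271,
  F = 18.99840320
)

#' Monoisotopic mass of an elemental composition
#'
#' Sums most-abundant-isotope masses over a composition string such as
#' `"C16H27O7"`. An empty string has mass 0. Additive by construction:
#' mass(A) + mass(B) equals the mass of the concatenated composition.
#'
#' @param formula character vector of composition strings over
#'   C, H, N, O, P, S (plus Na, K, Cl, F; extensible via `extra`).
#' @param extra optional named numeric vector of additional element
#'   monoisotopic masses.
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' formulaMass("H2O")       # 18.010565
#' formulaMass("C16H27O7")  # Tetranor-PGFM anion composition
#' @export
formulaMass <- function(formula, extra = NULL) {
  masses <- c(.monoisotopicMasses, extra)
  vapply(as.character(formula), function(f) {
    if (nchar(f) == 0) return(0)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(f)) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    total <- 0
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nchar(cnt) == 0) 1L else as.integer(cnt)
      if (!el %in% names(masses)) {
        stop("unknown element symbol '", el, "' in formula ", f,
             call. = FALSE)
      }
      total <- total + masses[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Signed mass error in parts per million
#'
#' 1e6 * (observed - theoretical) / theoretical.
#'
#' @param theoretical theoretical mass in Da, > 0.
#' @param observed observed mass in Da.
#' @return signed ppm error.
#' @examples
#' ppmError(400.0000, 400.0010)  # 2.5
#' @export
ppmError <- function(theoretical, observed) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Rank class-discriminant m/z features
#'
#' Orders the entries of a difference spectrum ([differenceSpectrum()];
#' mean NILM minus mean SIL) by absolute magnitude and tags each feature
#' with the class it favours: NILM when positive, SIL when negative.
#' Zero entries are never ranked.
#'
#' @param diff data.frame with columns `mz` and `difference`.
#' @param topN number of features to return; clipped with a warning when it
#'   exceeds the number of nonzero entries.
#' @return data.frame with columns `mz`, `difference`, `favoredClass`,
#'   strongest features first.
#' @export
rankDiscriminantFeatures <- function(diff, topN = 5) {
  stopifnot(all(c("mz", "difference") %in% names(diff)))
  nz <- diff[diff$difference != 0, , drop = FALSE]
  if (topN > nrow(nz)) {
    warning("topN clipped from ", topN, " to ", nrow(nz),
            " nonzero features", call. = FALSE)
    topN <- nrow(nz)
  }
  ord <- order(abs(nz$difference), decreasing = TRUE)
  out <- nz[ord[seq_len(topN)], , drop = FALSE]
  out$favoredClass <- ifelse(out$difference > 0, .negLabel, .posLabel)
  rownames(out) <- NULL
  out
}

#' Packaged lipid reference table
#'
#' Loads the reference CSV shipped with the package (columns `formula`,
#' `name`, `lipid_class`, `assigned_class`) and precomputes the theoretical
#' monoisotopic mass of every composition. Formulas are treated as the
#' intact detected-ion compositions: no adduct arithmetic is applied by
#' default because the ion convention behind vendor-reported mass errors
#' is not standardised (see the package vignette). An adduct mode is
#' available for users who know their convention.
#'
#' @param path CSV path; defaults to the table shipped in `extdata`.
#' @param adduct `"none"` (default), `"M+H"` or `"M+Na"`; when set, the
#'   adduct mass minus the electron mass is added to each theoretical
#'   mass.
#' @return data.frame with an added `theoretical_mass` column.
#' @export
lipidReference <- function(path = system.file("extdata",
                                              "lipid_reference.csv",
                                              package = "lipoclass"),
                           adduct = c("none", "M+H", "M+Na")) {
  adduct <- match.arg(adduct)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("formula", "name", "lipid_class", "assigned_class")
                %in% names(ref)))
  ref$theoretical_mass <- formulaMass(ref$formula)
  electron <- 0.00054857990907
  if (adduct == "M+H") {
    ref$theoretical_mass <- ref$theoretical_mass +
      .monoisotopicMasses[["H"]] - electron
  } else if (adduct == "M+Na") {
    ref$theoretical_mass <- ref$theoretical_mass +
      .monoisotopicMasses[["Na"]] - electron
  }
  ref
}

#' Match ranked features against a lipid reference table
#'
#' Each ranked feature is matched to the reference entry with the smallest
#' absolute ppm error, provided that error is within `tolPpm`; features
#' with no entry inside the tolerance are reported unmatched. A match with
#' |error| > tolPpm is never assigned.
#'
#' @param ranked output of [rankDiscriminantFeatures()].
#' @param reference reference table from [lipidReference()] (or any
#'   data.frame with the same columns plus `theoretical_mass`).
#' @param tolPpm match tolerance in ppm (default 10, wide enough to absorb
#'   uncertainty in the detected-ion convention).
#' @return data.frame mirroring the published annotation layout:
#'   `mz_observed`, `error_ppm`, `formula`, `name`, `lipid_class`,
#'   `assigned_class`, `favored_class`, `matched`.
#' @export
matchReference <- function(ranked, reference = lipidReference(),
                           tolPpm = 10) {
  stopifnot(tolPpm >= 0, "theoretical_mass" %in% names(reference))
  rows <- lapply(seq_len(nrow(ranked)), function(i) {
    mz <- ranked$mz[i]
    err <- ppmError(reference$theoretical_mass, mz)
    j <- which.min(abs(err))
    if (length(j) == 1 && abs(err[j]) <= tolPpm) {
      data.frame(mz_observed = mz, error_ppm = err[j],
                 formula = reference$formula[j], name = reference$name[j],
                 lipid_class = reference$lipid_class[j],
                 assigned_class = reference$assigned_class[j],
                 favored_class = ranked$favoredClass[i], matched = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mz_observed = mz, error_ppm = NA_real_,
                 formula = NA_character_, name = NA_character_,
                 lipid_class = NA_character_,
                 assigned_class = NA_character_,
                 favored_class = ranked$favoredClass[i], matched = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
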
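#' @title Total labeling and enrichment time series
#' @description Conversion of isotopomer intensity vectors into per-peptide
#'   total-labeling series, with the quantifiability filters used for
#'   heavy-water MS1 kinetics (intensity window, minimum time points).
#' @name enrichment
NULL

#' Total deuterium labeling of an isotopomer vector
#'
#' `I = 1 - M0 / sum(Mj)`: the fraction of peptide ion signal outside the
#' monoisotopic peak.  Scale-invariant, so raw ion counts and fractional
#' abundances give identical values.
#'
#' @param intensities Numeric vector `M0, M1, ...` (length >= 2), all
#'   entries non-negative, positive sum.
#' @return Fraction in `[0, 1)`.
#' @examples
#' total_labeling(c(0.8, 0.15, 0.05))  # 0.20
#' @export
total_labeling <- function(intensities) {
  x <- as.numeric(intensities)
  if (length(x) < 2L) stop("need at least 2 isotopomer intensities")
  if (anyNA(x)) stop("missing intensity values")
  if (any(x < 0)) stop("negative isotopomer intensity")
  s <- sum(x)
  if (s <= 0) stop("all-zero isotopomer vector")
  1 - x[1] / s
}

#' Build the enrichment series of one peptide time course
#'
#' Applies [total_labeling()] per time point of a single peptide's
#' isotopomer time course.  Time points whose isotopomer vector is all zero
#' are dropped and flagged rather than imputed.  The measured pre-label
#' baseline is recorded as `I0`; the theoretical natural-abundance baseline
#' is not substituted for it (it is a QC comparison, not a datum).
#'
#' @param tc data.frame with columns `time_h`, and isotopomer intensity
#'   columns `m0`, `m1`, ... for one peptide; one row per time point.
#' @return data.frame with columns `time_h`, `I`, `total_intensity`, `qc`
#'   (`"ok"` or `"zero_intensity"`), ordered by time, with attributes
#'   `baseline` (measured I at t = 0) and `n_dropped`.
#' @export
enrichment_series <- function(tc) {
  stopifnot(is.data.frame(tc), "time_h" %in% names(tc))
  mcols <- grep("^m[0-9]+$", names(tc), value = TRUE)
  if (length(mcols) < 2L) stop("need at least columns m0 and m1")
  mcols <- mcols[order(as.integer(sub("m", "", mcols)))]
  tc <- tc[order(tc$time_h), , drop = FALSE]
  if (anyDuplicated(tc$time_h)) stop("duplicate time points in series")
  if (!any(tc$time_h == 0)) stop("series lacks a baseline (t = 0) point")
  if (nrow(tc) < 2L) stop("baseline-only series carries no kinetic information")
  mm <- as.matrix(tc[, mcols, drop = FALSE])
  if (anyNA(mm) || any(mm < 0)) stop("invalid (negative or missing) intensity")
  tot <- rowSums(mm)
  keep <- tot > 0
  I <- rep(NA_real_, nrow(tc))
  I[keep] <- 1 - mm[keep, 1] / tot[keep]
  out <- data.frame(
    time_h = tc$time_h,
    I = I,
    total_intensity = tot,
    qc = ifelse(keep, "ok", "zero_intensity"),
    stringsAsFactors = FALSE
  )
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (!any(out$time_h == 0)) stop("baseline point failed QC; series unusable")
  rownames(out) <- NULL
  attr(out, "baseline") <- out$I[out$time_h == 0][1]
  attr(out, "n_dropped") <- dropped
  out
}

#' Quantifiability filter for an enrichment series
#'
#' A series is quantifiable when at least `min_points` time points each have
#' a summed isotopomer intensity inside the ion-count window (defaults:
#' 5 points, 1e6 to 1e8 ion counts).  The window is applied to the summed
#' intensity of the extracted isotopomers, the robust scale-relevant
#' quantity.  The first failed criterion names the rejection.
#'
#' @param series Output of [enrichment_series()].
#' @param min_points Minimum number of in-window time points.
#' @param intensity_window Length-2 numeric `c(low, high)` in ion counts.
#' @return list with `accepted` (logical), `reason` (`NA` when accepted),
#'   `n_pass`, and per-point logical `in_window`.
#' @export
filter_series <- function(series, min_points = 5L,
                          intensity_window = c(1e6, 1e8)) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "total_intensity") %in% names(series)),
            length(intensity_window) == 2L,
            intensity_window[1] < intensity_window[2])
  inw <- series$total_intensity >= intensity_window[1] &
    series$total_intensity <= intensity_window[2]
  n_pass <- sum(inw)
  if (nrow(series) < min_points) {
    return(list(accepted = FALSE, reason = "too few time points",
                n_pass = n_pass, in_window = inw))
  }
  if (n_pass < min_points) {
    reason <- if (any(series$total_intensity < intensity_window[1])) {
      "intensity below window"
    } else {
      "intensity above window"
    }
    return(list(accepted = FALSE, reason = reason,
                n_pass = n_pass, in_window = inw))
  }
  list(accepted = TRUE, reason = NA_character_, n_pass = n_pass,
       in_window = inw)
}
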
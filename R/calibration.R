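#' Find acceleration peaks inside the calibration band
#'
#' The smallest acceleration peaks an infant produces that reflect movement
#' (rather than noise) are consistent within a recording but vary between
#' roughly 1.00 and 3.25 m/s^2 across recordings. Calibration therefore
#' collects, separately, all positive local maxima of the detrended
#' acceleration magnitude with values in `[band_low, band_high]` and all
#' negative local minima with values in `[-band_high, -band_low]` (band
#' endpoints inclusive).
#'
#' A peak is a strict local extremum over three samples; a flat-topped
#' plateau counts once, at its value.
#'
#' @param x Detrended acceleration magnitude series (baseline 0), m/s^2.
#' @param band_low,band_high Band edges in m/s^2 (defaults 1.00 and 3.25).
#' @return List with numeric vectors `positive` (peak values in
#'   `[band_low, band_high]`) and `negative` (peak values in
#'   `[-band_high, -band_low]`).
#' @export
find_band_peaks <- function(x, band_low = 1.00, band_high = 3.25) {
  if (band_low >= band_high) {
    abort("band_low must be smaller than band_high",
          class = "legmov_validation_error")
  }
  if (length(x) < 3) {
    return(list(positive = numeric(0), negative = numeric(0)))
  }
  # collapse exact plateaus so each counts once
  r <- rle(x)
  v <- r$values
  nr <- length(v)
  if (nr < 3) {
    return(list(positive = numeric(0), negative = numeric(0)))
  }
  mid <- 2:(nr - 1)
  is_max <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
  is_min <- v[mid] < v[mid - 1] & v[mid] < v[mid + 1]
  maxima <- v[mid][is_max]
  minima <- v[mid][is_min]
  list(
    positive = maxima[maxima >= band_low & maxima <= band_high],
    negative = minima[minima <= -band_low & minima >= -band_high]
  )
}

#' Turn band-limited peak statistics into detection thresholds
#'
#' For each side of the baseline, the threshold is the mean of the in-band
#' peak values minus their standard deviation (n-1 denominator), so that the
#' threshold sits below the typical small movement peak but above sensor
#' noise. The negative side is computed on absolute values and negated, so
#' both thresholds lie between the baseline and the peaks.
#'
#' @param pos_peaks,neg_peaks Numeric vectors of in-band peak values
#'   (positive values and negative values respectively), as returned by
#'   [find_band_peaks()].
#' @param band_low,band_high The band used to collect the peaks; recorded in
#'   the result and used for the degenerate-case clamp.
#' @return A one-row tibble of class `calibrated_thresholds` with columns
#'   `pos_threshold` (> 0), `neg_threshold` (< 0), `n_pos_peaks`,
#'   `n_neg_peaks`, `pos_mean`, `pos_sd`, `neg_mean_abs`, `neg_sd_abs`.
#' @examples
#' thresholds_from_peaks(c(1.2, 2.0, 2.8), c(-1.2, -2.0, -2.8))
#' @export
thresholds_from_peaks <- function(pos_peaks, neg_peaks,
                                  band_low = 1.00, band_high = 3.25) {
  if (length(pos_peaks) == 0 || length(neg_peaks) == 0) {
    abort(
      paste0(
        "calibration failed: no in-band ",
        if (length(pos_peaks) == 0) "positive" else "negative",
        " acceleration peaks; supply thresholds manually or widen the band"
      ),
      class = "legmov_calibration_error"
    )
  }
  one_side <- function(values, side) {
    m <- mean(values)
    s <- if (length(values) >= 2) sd(values) else {
      warn(paste0("single ", side, " in-band peak: sd taken as 0"))
      0
    }
    thr <- m - s
    if (thr <= 0) {
      warn(paste0(side, " threshold mean - sd is non-positive; clamped to band_low/2"))
      thr <- band_low / 2
    }
    list(mean = m, sd = s, threshold = thr)
  }
  pos <- one_side(pos_peaks, "positive")
  neg <- one_side(abs(neg_peaks), "negative")
  out <- tibble(
    pos_threshold = pos$threshold,
    neg_threshold = -neg$threshold,
    n_pos_peaks = length(pos_peaks),
    n_neg_peaks = length(neg_peaks),
    pos_mean = pos$mean,
    pos_sd = pos$sd,
    neg_mean_abs = neg$mean,
    neg_sd_abs = neg$sd
  )
  structure(out, class = c("calibrated_thresholds", class(out)),
            band = c(low = band_low, high = band_high))
}

#' Calibrate per-recording acceleration thresholds
#'
#' Runs [preprocess()] (unless given an already-preprocessed
#' `magnitude_series`), collects in-band peaks over the *entire* wear period
#' — including sleep — with [find_band_peaks()], and derives the positive
#' and negative thresholds with [thresholds_from_peaks()]. Thresholds are
#' unique to each leg at each visit: they adapt to each infant's
#' acceleration profile.
#'
#' @param recording An [imu_recording()] or a `magnitude_series` from
#'   [preprocess()].
#' @inheritParams find_band_peaks
#' @return A `calibrated_thresholds` tibble (see
#'   [thresholds_from_peaks()]).
#' @examples
#' rec <- simulate_imu(sim_config(duration = 120), seed = 1)$left
#' calibrate(rec)
#' @export
calibrate <- function(recording, band_low = 1.00, band_high = 3.25) {
  mag <- if (inherits(recording, "magnitude_series")) recording else preprocess(recording)
  peaks <- find_band_peaks(mag$accel_mag, band_low, band_high)
  withCallingHandlers(
    thresholds_from_peaks(peaks$positive, peaks$negative, band_low, band_high),
    legmov_calibration_error = function(e) {
      abort(
        paste0(conditionMessage(e), " [", length(peaks$positive),
               " positive / ", length(peaks$negative),
               " negative in-band peaks over ", nrow(mag), " samples]"),
        class = "legmov_calibration_error"
      )
    }
  )
}
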
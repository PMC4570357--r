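#' Vector magnitudes of tri-axial signals
#'
#' Movement can produce acceleration or rotation on any axis, so detection
#' works on the Euclidean norm of the three axes, which is invariant to
#' sensor orientation: `sqrt(ax^2 + ay^2 + az^2)` per sample (and the same
#' for angular velocity).
#'
#' @param ax,ay,az Numeric vectors of equal length, m/s^2.
#' @param gx,gy,gz Numeric vectors of equal length, rad/s.
#' @return Numeric vector of per-sample magnitudes (non-negative).
#' @examples
#' accel_magnitude(3, 4, 0) # 5
#' gyro_magnitude(2, 3, 6)  # 7
#' @export
accel_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ax) != length(az)) {
    abort("acceleration channels must have equal length",
          class = "legmov_validation_error")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' @rdname accel_magnitude
#' @export
gyro_magnitude <- function(gx, gy, gz) {
  if (length(gx) != length(gy) || length(gx) != length(gz)) {
    abort("gyroscope channels must have equal length",
          class = "legmov_validation_error")
  }
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Remove linear drift from a magnitude series
#'
#' Fits one least-squares line over the whole series and subtracts it,
#' setting the signal baseline to 0. Residuals sum to zero and are
#' orthogonal to time, so detrending is idempotent.
#'
#' @param x Numeric series (length >= 2).
#' @param t Time axis, seconds; defaults to the sample index.
#' @return List with `residuals` (same length as `x`) and `coefficients`
#'   (named `intercept` in the units of `x` and `slope` in units of `x` per
#'   unit of `t`).
#' @examples
#' detrend_linear(c(0, 1, 0), t = c(0, 1, 2))$residuals # -1/3, 2/3, -1/3
#' @export
detrend_linear <- function(x, t = seq_along(x) - 1) {
  if (length(x) < 2) {
    abort("detrending needs at least 2 samples", class = "legmov_validation_error")
  }
  if (length(t) != length(x)) {
    abort("x and t must have equal length", class = "legmov_validation_error")
  }
  fit <- stats::lm.fit(cbind(1, t), x)
  co <- fit$coefficients
  list(
    residuals = unname(fit$residuals),
    coefficients = c(intercept = unname(co[1]), slope = unname(co[2]))
  )
}

#' Preprocess a recording into the detector's magnitude series
#'
#' Computes the acceleration and angular-velocity magnitudes over the whole
#' wear period, then removes linear drift from the acceleration magnitude so
#' its baseline sits at 0. The gyro magnitude is left raw (it is only ever
#' compared against a floor, and its baseline is not referenced by the
#' detector). No low-pass filtering is applied.
#'
#' @param recording An [imu_recording()].
#' @return A tibble of class `magnitude_series` with columns `t`,
#'   `accel_mag` (detrended acceleration magnitude, m/s^2, baseline 0) and
#'   `gyro_mag` (rad/s, >= 0); attributes carry the leg, sample rate, wear
#'   interval and the fitted drift coefficients.
#' @examples
#' rec <- simulate_imu(sim_config(duration = 30), seed = 1)$left
#' mag <- preprocess(rec)
#' abs(mean(mag$accel_mag)) < 1e-8
#' @export
preprocess <- function(recording) {
  stopifnot(inherits(recording, "imu_recording"))
  amag <- accel_magnitude(recording$ax, recording$ay, recording$az)
  gmag <- gyro_magnitude(recording$gx, recording$gy, recording$gz)
  det <- detrend_linear(amag, recording$t)
  out <- tibble(
    t = recording$t,
    accel_mag = det$residuals,
    gyro_mag = gmag
  )
  structure(
    out,
    class = c("magnitude_series", class(out)),
    leg = attr(recording, "leg"),
    sample_rate = attr(recording, "sample_rate"),
    wear_start = attr(recording, "wear_start"),
    wear_end = attr(recording, "wear_end"),
    detrend_coefficients = det$coefficients
  )
}
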
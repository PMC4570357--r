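# Builders for small in-code fixtures used across the suite.

make_recording <- function(ax, ay, az, gx = 0, gy = 0, gz = 0,
                           leg = "left", sample_rate = 20) {
  n <- max(lengths(list(ax, ay, az, gx, gy, gz)))
  rec <- data.frame(
    t = (seq_len(n) - 1) / sample_rate,
    ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
    gx = rep_len(gx, n), gy = rep_len(gy, n), gz = rep_len(gz, n)
  )
  imu_recording(rec, leg = leg, sample_rate = sample_rate)
}

# A magnitude series built directly from a zero-baseline acceleration trace
# and a gyro trace, bypassing preprocess(); used to hand-feed the detector.
make_mag <- function(accel, gyro = 1, sample_rate = 20, leg = "left") {
  n <- length(accel)
  out <- tibble::tibble(
    t = (seq_len(n) - 1) / sample_rate,
    accel_mag = accel,
    gyro_mag = rep_len(gyro, n)
  )
  structure(
    out,
    class = c("magnitude_series", class(out)),
    leg = leg, sample_rate = sample_rate,
    wear_start = as.POSIXct("2015-03-01 08:00:00", tz = "UTC"),
    wear_end = as.POSIXct("2015-03-01 08:00:00", tz = "UTC") + n / sample_rate,
    detrend_coefficients = c(intercept = 0, slope = 0)
  )
}

make_thresholds <- function(pos = 1, neg = -pos) {
  thresholds_from_peaks(c(pos, pos), c(neg, neg))
}

# An event table shaped like detect_movements() output, for scoring tests.
make_events <- function(start_times, leg = "left", sample_rate = 20) {
  idx <- as.integer(round(start_times * sample_rate)) + 1L
  out <- tibble::tibble(
    leg = rep_len(leg, length(start_times)),
    start_index = idx,
    end_index = idx + 1L,
    start_time = start_times,
    end_time = start_times + 1 / sample_rate,
    trigger_side = "positive"
  )
  structure(out, class = c("movement_events", class(out)),
            diagnostics = list(discarded_open_event = FALSE))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform random orthogonal matrix
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

# Evenly spaced stand-in times (deterministic, RNG-free).
runif_fixed <- function(n, lo, hi) lo + (seq_len(n) - 0.5) * (hi - lo) / n
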
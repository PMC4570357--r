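#' Detect leg movements in a preprocessed magnitude series
#'
#' A movement *starts* at the first sample where the detrended acceleration
#' magnitude exceeds the positive threshold or drops below the negative
#' threshold while the angular-velocity magnitude is simultaneously above
#' `gyro_floor` (default 0, the literal "rotation present" condition).
#' Requiring concurrent rotation rejects background motion from cars,
#' strollers and mechanical swings, where predominately linear acceleration
#' is present. The movement *ends* once two baseline (zero) crossings of the
#' acceleration magnitude in different directions have occurred after the
#' start — so each pause or change of direction of the limb closes one
#' movement and a new exceedance starts the next (a supine kick of flexion
#' then extension counts as two movements).
#'
#' Discrete-sample conventions: a crossing occurs between samples `k`,
#' `k + 1` when the signs of both samples are nonzero and differ; exact-zero
#' samples inherit the previous nonzero sign, so a graze of the baseline is
#' not a crossing. Crossings are counted from the start sample onwards. The
#' event ends at the later sample of the pair completing the second
#' qualifying crossing, and scanning resumes at the following sample, so
#' events never overlap. If the recording ends mid-event the open event is
#' discarded and reported in the `diagnostics` attribute.
#'
#' @param mag A `magnitude_series` from [preprocess()].
#' @param thresholds A `calibrated_thresholds` row from [calibrate()].
#' @param gyro_floor Angular-velocity magnitude that must be exceeded at the
#'   start sample, rad/s. Default 0; real gyros are noisy, so a small
#'   positive floor is available as an escape hatch.
#' @return A tibble of class `movement_events` with columns `leg`,
#'   `start_index`, `end_index` (1-based, inclusive), `start_time`,
#'   `end_time` (s) and `trigger_side` (`"positive"`/`"negative"`), ordered
#'   and non-overlapping. Attribute `diagnostics` lists any discarded open
#'   event.
#' @examples
#' sim <- simulate_imu(sim_config(duration = 60), seed = 1)
#' mag <- preprocess(sim$left)
#' detect_movements(mag, calibrate(mag))
#' @export
detect_movements <- function(mag, thresholds, gyro_floor = 0) {
  stopifnot(inherits(mag, "magnitude_series"))
  x <- mag$accel_mag
  g <- mag$gyro_mag
  n <- length(x)
  pos_thr <- thresholds$pos_threshold
  neg_thr <- thresholds$neg_threshold

  trigger_idx <- which((x > pos_thr | x < neg_thr) & g > gyro_floor)

  # zero-inherited sign sequence: exact zeros take the previous nonzero sign
  s <- sign(x)
  nz <- s != 0
  filled <- c(0, s[nz])[cumsum(nz) + 1]
  # pair-start indices of baseline crossings; consecutive crossings of the
  # filled sign sequence necessarily alternate in direction, so the second
  # crossing at or after a start always differs in direction from the first
  k <- seq_len(n - 1)
  cross_k <- k[filled[k] != 0 & filled[k + 1] != 0 & filled[k] != filled[k + 1]]

  starts <- integer(0)
  ends <- integer(0)
  open_discarded <- FALSE
  p <- 1L
  repeat {
    si <- findInterval(p - 0.5, trigger_idx) + 1L
    if (si > length(trigger_idx)) break
    start <- trigger_idx[si]
    cj <- findInterval(start - 0.5, cross_k) + 1L
    if (cj + 1L > length(cross_k)) {
      open_discarded <- TRUE
      break
    }
    end <- cross_k[cj + 1L] + 1L
    starts <- c(starts, start)
    ends <- c(ends, end)
    p <- end + 1L
  }

  out <- tibble(
    leg = rep(attr(mag, "leg") %||% NA_character_, length(starts)),
    start_index = starts,
    end_index = ends,
    start_time = mag$t[starts],
    end_time = mag$t[ends],
    trigger_side = ifelse(x[starts] > pos_thr, "positive", "negative")
  )
  structure(out, class = c("movement_events", class(out)),
            diagnostics = list(discarded_open_event = open_discarded))
}

#' Literal reference implementation of the movement detector
#'
#' An unoptimized sample-by-sample transcription of the detection rules,
#' tracking the up/down crossing flags explicitly. It exists as an
#' independent cross-check for [detect_movements()] in the test suite and is
#' far too slow for full-day recordings.
#'
#' @inheritParams detect_movements
#' @return As [detect_movements()].
#' @export
detect_movements_reference <- function(mag, thresholds, gyro_floor = 0) {
  stopifnot(inherits(mag, "magnitude_series"))
  x <- mag$accel_mag
  g <- mag$gyro_mag
  n <- length(x)
  pos_thr <- thresholds$pos_threshold
  neg_thr <- thresholds$neg_threshold

  last_sign_at <- function(i) {
    for (j in seq(i, 1)) if (x[j] != 0) return(sign(x[j]))
    0
  }

  starts <- integer(0)
  ends <- integer(0)
  open_discarded <- FALSE
  i <- 1L
  while (i <= n) {
    is_start <- (x[i] > pos_thr || x[i] < neg_thr) && g[i] > gyro_floor
    if (!is_start) {
      i <- i + 1L
      next
    }
    start <- i
    cur <- last_sign_at(start)
    seen_down <- FALSE
    seen_up <- FALSE
    end <- NA_integer_
    k <- start
    while (k <= n - 1L) {
      s_next <- sign(x[k + 1L])
      if (s_next != 0 && cur != 0 && s_next != cur) {
        if (cur > 0) seen_down <- TRUE else seen_up <- TRUE
        if (seen_down && seen_up) {
          end <- k + 1L
          break
        }
      }
      if (s_next != 0) cur <- s_next
      k <- k + 1L
    }
    if (is.na(end)) {
      open_discarded <- TRUE
      break
    }
    starts <- c(starts, start)
    ends <- c(ends, end)
    i <- end + 1L
  }

  out <- tibble(
    leg = rep(attr(mag, "leg") %||% NA_character_, length(starts)),
    start_index = starts,
    end_index = ends,
    start_time = mag$t[starts],
    end_time = mag$t[ends],
    trigger_side = ifelse(x[starts] > pos_thr, "positive", "negative")
  )
  structure(out, class = c("movement_events", class(out)),
            diagnostics = list(discarded_open_event = open_discarded))
}

#' Awake time within the wear interval
#'
#' Total logged sleep overlapping the (half-open) wear interval is rounded
#' to the nearest 10 minutes and subtracted from the wear duration. Time not
#' logged as asleep counts as awake; with no log at all the whole wear
#' period is awake.
#'
#' @param log An [activity_log()] or `NULL`.
#' @param wear_start,wear_end Clock timestamps (`POSIXct`) of the wear
#'   interval.
#' @return Awake time in hours.
#' @examples
#' ws <- as.POSIXct("2015-03-01 08:00:00", tz = "UTC")
#' log <- activity_log(data.frame(
#'   start = ws + 4 * 3600, end = ws + 6 * 3600, state = "asleep"
#' ))
#' awake_hours(log, ws, ws + 10 * 3600) # 8
#' @export
awake_hours <- function(log, wear_start, wear_end) {
  wear_h <- as.numeric(difftime(wear_end, wear_start, units = "hours"))
  if (wear_h <= 0) {
    abort("wear interval has non-positive duration",
          class = "legmov_validation_error")
  }
  if (is.null(log)) return(wear_h)
  stopifnot(inherits(log, "activity_log"))
  naps <- log[log$state == "asleep", , drop = FALSE]
  if (nrow(naps) == 0) return(wear_h)
  overlap_h <- pmax(
    0,
    as.numeric(difftime(pmin(naps$end, wear_end),
                        pmax(naps$start, wear_start), units = "hours"))
  )
  asleep_min <- round_half_away(sum(overlap_h) * 60 / 10) * 10
  wear_h - asleep_min / 60
}

#' Summarize one day of wear for one leg
#'
#' Runs preprocessing, calibration (unless thresholds are supplied) and
#' detection over the entire wear period, then normalizes the count by awake
#' time. Movements detected during logged sleep are *included* in the count
#' (an infant waking briefly and moving is real movement); sleep enters only
#' through the awake-hours denominator of the rate.
#'
#' @param recording An [imu_recording()].
#' @param thresholds Optional `calibrated_thresholds`; calibrated from the
#'   recording when `NULL`.
#' @param log An [activity_log()] or `NULL` (all wear time awake).
#' @inheritParams detect_movements
#' @return A one-row tibble of class `day_result` with columns `leg`,
#'   `n_movements`, `wear_hours`, `awake_hours`, `rate_per_awake_hour`;
#'   the detected events travel in the `events` attribute (see
#'   [day_events()]).
#' @export
summarize_day <- function(recording, thresholds = NULL, log = NULL,
                          gyro_floor = 0) {
  mag <- preprocess(recording)
  if (is.null(thresholds)) thresholds <- calibrate(mag)
  events <- detect_movements(mag, thresholds, gyro_floor = gyro_floor)
  ws <- attr(recording, "wear_start")
  we <- attr(recording, "wear_end")
  wear_h <- as.numeric(difftime(we, ws, units = "hours"))
  awake_h <- awake_hours(log, ws, we)
  if (awake_h <= 0) {
    abort("awake time is zero: movement rate is undefined",
          class = "legmov_validation_error")
  }
  out <- tibble(
    leg = attr(recording, "leg"),
    n_movements = nrow(events),
    wear_hours = wear_h,
    awake_hours = awake_h,
    rate_per_awake_hour = nrow(events) / awake_h
  )
  structure(out, class = c("day_result", class(out)),
            events = events, thresholds = thresholds)
}

#' @rdname summarize_day
#' @param x A `day_result`.
#' @export
day_events <- function(x) attr(x, "events")
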
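#' Pipeline run configuration
#'
#' Bundles the tunable detector settings: the peak-calibration band, the
#' angular-velocity floor, and the event-matching tolerance used when
#' ground truth is scored. The defaults are the ones every module documents;
#' a `run_config` round-trips through JSON unchanged.
#'
#' @param band Calibration band `c(low, high)`, m/s^2.
#' @param gyro_floor Angular-velocity start gate, rad/s.
#' @param tolerance Event-matching tolerance, s.
#' @param seed Optional integer seed echoed into reports.
#' @return A list of class `run_config`.
#' @export
run_config <- function(band = c(1.00, 3.25), gyro_floor = 0,
                       tolerance = 0.25, seed = NULL) {
  stopifnot(length(band) == 2, band[1] < band[2], gyro_floor >= 0,
            tolerance >= 0)
  structure(list(band = band, gyro_floor = gyro_floor,
                 tolerance = tolerance, seed = seed),
            class = "run_config")
}

#' Run the full detection pipeline for one day of wear
#'
#' Calibrates, detects and rate-normalizes each supplied leg:
#' [preprocess()] then [calibrate()] then [detect_movements()] then
#' [summarize_day()]. Both legs are expected; a single leg is accepted with
#' a warning.
#'
#' @param left,right [imu_recording()]s (either may be `NULL`, not both).
#' @param log An [activity_log()] or `NULL` (all wear time counts as awake;
#'   flagged in the report diagnostics).
#' @param config A [run_config()].
#' @return A list of class `day_report` with elements `days` (one
#'   `day_result` row per leg), `events`, `thresholds` (one row per leg),
#'   `diagnostics` and `config`.
#' @export
run_pipeline <- function(left, right = NULL, log = NULL, config = run_config()) {
  recs <- list(left = left, right = right)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) {
    abort("at least one leg recording is required",
          class = "legmov_validation_error")
  }
  if (length(recs) == 1) {
    warn("only one leg supplied; bilateral recordings are expected")
  }
  per_leg <- lapply(recs, function(rec) {
    mag <- preprocess(rec)
    thr <- calibrate(mag, band_low = config$band[1], band_high = config$band[2])
    day <- summarize_day(rec, thresholds = thr, log = log,
                         gyro_floor = config$gyro_floor)
    list(day = day, thr = thr,
         discarded = attr(day_events(day), "diagnostics")$discarded_open_event)
  })
  days <- bind_rows(lapply(per_leg, function(p) as_tibble(p$day)))
  events <- bind_rows(lapply(per_leg, function(p) as_tibble(day_events(p$day))))
  thresholds <- bind_rows(lapply(names(per_leg), function(lg) {
    mutate(as_tibble(per_leg[[lg]]$thr), leg = lg, .before = 1)
  }))
  structure(
    list(
      days = days,
      events = events,
      thresholds = thresholds,
      diagnostics = list(
        no_log = is.null(log),
        discarded_open_event = vapply(per_leg, function(p) p$discarded, logical(1))
      ),
      config = unclass(config),
      version = as.character(utils::packageVersion("legmov"))
    ),
    class = "day_report"
  )
}

#' @export
print.day_report <- function(x, ...) {
  cat("Daily leg-movement report (legmov ", x$version, ")\n", sep = "")
  print(x$days)
  invisible(x)
}

#' Serialize a day report to JSON
#'
#' Writes a deterministic JSON report (thresholds, per-leg counts and
#' rates, diagnostics and the config echo). Event tables are included only
#' when `events = TRUE`.
#'
#' @param report A `day_report` from [run_pipeline()].
#' @param path Output path.
#' @param events Include the per-event table?
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, events = FALSE) {
  stopifnot(inherits(report, "day_report"))
  payload <- list(
    version = report$version,
    config = report$config,
    thresholds = report$thresholds,
    days = report$days,
    diagnostics = report$diagnostics
  )
  if (events) payload$events <- report$events
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
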
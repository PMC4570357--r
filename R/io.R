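#' Construct an IMU recording
#'
#' An `imu_recording` is a tibble holding one leg's six-channel inertial time
#' series: columns `t` (seconds since the start of wear), `ax`, `ay`, `az`
#' (linear acceleration, m/s^2) and `gx`, `gy`, `gz` (angular velocity,
#' rad/s), sampled on a uniform grid. The leg side, sample rate and the wear
#' interval (clock time) travel as attributes so that downstream joins with
#' the activity log are unambiguous.
#'
#' @param data Data frame with numeric columns `t,ax,ay,az,gx,gy,gz`.
#' @param leg `"left"` or `"right"`.
#' @param sample_rate Sampling rate in Hz (default 20).
#' @param wear_start,wear_end Clock timestamps (`POSIXct`) of sensor wear.
#'   `wear_start` defaults to an arbitrary morning clock time; `wear_end`
#'   defaults to `wear_start` plus the recording span.
#' @return A tibble of class `imu_recording`.
#' @examples
#' rec <- imu_recording(
#'   data.frame(t = c(0, 0.05, 0.1), ax = 0, ay = 0, az = 9.81,
#'              gx = 0, gy = 0, gz = 0),
#'   leg = "left"
#' )
#' wear_interval(rec)
#' @export
imu_recording <- function(data, leg = c("left", "right"), sample_rate = 20,
                          wear_start = NULL, wear_end = NULL) {
  leg <- match.arg(leg)
  required <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing recording column(s): ", paste(missing_cols, collapse = ", ")),
      class = "legmov_parse_error"
    )
  }
  data <- as_tibble(data)[required]
  for (col in required) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))[1]
      abort(
        paste0("non-numeric value in column '", col, "' (row ", bad %||% NA, ")"),
        class = "legmov_parse_error"
      )
    }
  }
  if (nrow(data) < 2) {
    abort("a recording needs at least 2 samples", class = "legmov_parse_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("sample_rate must be a single positive number", class = "legmov_parse_error")
  }
  dt <- diff(data$t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    abort(paste0("time base not strictly increasing at row ", bad),
          class = "legmov_time_base_error")
  }
  expected_dt <- 1 / sample_rate
  off <- which(abs(dt - expected_dt) > 1e-6)
  if (length(off) > 0) {
    abort(
      paste0("non-uniform time base at row ", off[1] + 1, ": step ",
             signif(dt[off[1]], 6), " s, expected ", signif(expected_dt, 6), " s"),
      class = "legmov_time_base_error"
    )
  }
  if (is.null(wear_start)) {
    wear_start <- as.POSIXct("2015-03-01 08:00:00", tz = "UTC")
  }
  if (is.null(wear_end)) {
    wear_end <- wear_start + (data$t[nrow(data)] - data$t[1]) + 1 / sample_rate
  }
  structure(
    data,
    class = c("imu_recording", class(data)),
    leg = leg,
    sample_rate = sample_rate,
    wear_start = wear_start,
    wear_end = wear_end
  )
}

#' @rdname imu_recording
#' @param x An `imu_recording`.
#' @export
wear_interval <- function(x) {
  stopifnot(inherits(x, "imu_recording"))
  c(start = attr(x, "wear_start"), end = attr(x, "wear_end"))
}

#' @rdname imu_recording
#' @export
leg_side <- function(x) attr(x, "leg")

#' @rdname imu_recording
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' Read and write recording CSV files
#'
#' The native interchange format is a plain CSV with header
#' `t,ax,ay,az,gx,gy,gz` (units: s, m/s^2, rad/s). Units are taken at face
#' value; no g-to-m/s^2 conversion is applied. Vendor binary formats are out
#' of scope; export to this CSV first.
#'
#' @param path Path to a CSV file.
#' @inheritParams imu_recording
#' @return `read_imu_recording()` returns an `imu_recording`;
#'   `write_imu_recording()` returns `path` invisibly.
#' @export
read_imu_recording <- function(path, leg = c("left", "right"), sample_rate = 20,
                               wear_start = NULL, wear_end = NULL) {
  leg <- match.arg(leg)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "legmov_parse_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_double())),
    error = function(e) abort(paste0("cannot parse ", path, ": ", conditionMessage(e)),
                              class = "legmov_parse_error")
  )
  if (nrow(df) == 0) {
    abort(paste0("empty recording file: ", path), class = "legmov_parse_error")
  }
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(
      paste0("non-numeric value at row ", prob$row[1], ", column ", prob$col[1],
             " of ", path),
      class = "legmov_parse_error"
    )
  }
  imu_recording(df, leg = leg, sample_rate = sample_rate,
                wear_start = wear_start, wear_end = wear_end)
}

#' @rdname read_imu_recording
#' @param x An `imu_recording`.
#' @export
write_imu_recording <- function(x, path) {
  stopifnot(inherits(x, "imu_recording"))
  readr::write_csv(as_tibble(unclass_recording(x)), path)
  invisible(path)
}

unclass_recording <- function(x) {
  out <- x
  class(out) <- setdiff(class(out), c("imu_recording", "magnitude_series"))
  out
}

#' Construct or read a parent activity log
#'
#' The activity log records clock-time intervals labelled `asleep`, `awake`
#' or `background_motion` (cars, strollers, mechanical swings), with a
#' free-text note. Intervals are half-open `[start, end)`. Time not covered
#' by an `asleep` entry counts as awake: sleep is derived only from logged
#' naps.
#'
#' @param data Data frame with columns `start`, `end` (`POSIXct` or ISO-8601
#'   strings) and `state`; an optional `note` column is carried along.
#' @return A tibble of class `activity_log`.
#' @export
activity_log <- function(data) {
  required <- c("start", "end", "state")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing activity-log column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "legmov_parse_error")
  }
  data <- as_tibble(data)
  if (!"note" %in% names(data)) data$note <- NA_character_
  for (col in c("start", "end")) {
    if (!inherits(data[[col]], "POSIXct")) {
      parsed <- as.POSIXct(data[[col]], tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
      if (anyNA(parsed) && !all(is.na(data[[col]]))) {
        abort(paste0("unparseable timestamp in column '", col, "'"),
              class = "legmov_parse_error")
      }
      data[[col]] <- parsed
    }
  }
  valid_states <- c("asleep", "awake", "background_motion")
  bad_state <- setdiff(unique(data$state), valid_states)
  if (length(bad_state) > 0) {
    abort(paste0("unknown activity state: ", paste(bad_state, collapse = ", ")),
          class = "legmov_validation_error")
  }
  if (any(data$end <= data$start)) {
    bad <- which(data$end <= data$start)[1]
    abort(paste0("activity interval with end <= start at row ", bad),
          class = "legmov_validation_error")
  }
  naps <- data[data$state == "asleep", , drop = FALSE]
  if (nrow(naps) > 1) {
    naps <- naps[order(naps$start), ]
    overlap <- which(utils::head(naps$end, -1) > utils::tail(naps$start, -1))
    if (length(overlap) > 0) {
      abort("overlapping asleep intervals in activity log",
            class = "legmov_validation_error")
    }
  }
  structure(data[c("start", "end", "state", "note")],
            class = c("activity_log", class(data)))
}

#' @rdname activity_log
#' @param path CSV file with header `start,end,state,note` (ISO-8601 clock
#'   times).
#' @export
read_activity_log <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "legmov_parse_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          start = readr::col_character(),
                          end = readr::col_character(),
                          .default = readr::col_character()
                        ))
  activity_log(df)
}

#' Construct or read a ground-truth annotation set
#'
#' Ground truth for validation comes in two flavours. *Segment counts*
#' (columns `segment_start,segment_end,leg,count`) give the number of
#' movements an observer counted per leg in each scored interval — the
#' bookkeeping used when scoring against video observation. *Event times*
#' (columns `time,leg`) give individual movement onsets, as produced by the
#' simulator's ground truth.
#'
#' @param data Data frame in one of the two layouts above. Times are seconds
#'   on the recording axis.
#' @param mode `"segment_counts"` or `"event_times"`; inferred from the
#'   columns when `NULL`.
#' @return A tibble of class `annotation_set` with attribute `mode`.
#' @export
annotation_set <- function(data, mode = NULL) {
  data <- as_tibble(data)
  if (is.null(mode)) {
    mode <- if (all(c("segment_start", "segment_end", "count") %in% names(data))) {
      "segment_counts"
    } else if ("time" %in% names(data)) {
      "event_times"
    } else {
      abort("cannot infer annotation mode from columns",
            class = "legmov_parse_error")
    }
  }
  mode <- match.arg(mode, c("segment_counts", "event_times"))
  if (mode == "segment_counts") {
    required <- c("segment_start", "segment_end", "leg", "count")
    missing_cols <- setdiff(required, names(data))
    if (length(missing_cols) > 0) {
      abort(paste0("missing annotation column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "legmov_parse_error")
    }
    if (any(data$count < 0)) {
      abort("negative movement count in annotations",
            class = "legmov_validation_error")
    }
    if (any(data$segment_end <= data$segment_start)) {
      abort("annotation segment with non-positive duration",
            class = "legmov_validation_error")
    }
    data <- data[required]
  } else {
    required <- c("time", "leg")
    missing_cols <- setdiff(required, names(data))
    if (length(missing_cols) > 0) {
      abort(paste0("missing annotation column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "legmov_parse_error")
    }
    data <- arrange(data[required], .data$leg, .data$time)
  }
  structure(data, class = c("annotation_set", class(data)), mode = mode)
}

#' @rdname annotation_set
#' @param path CSV in either annotation layout.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "legmov_parse_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  annotation_set(df)
}

#' @rdname annotation_set
#' @param x An `annotation_set`.
#' @export
annotation_mode <- function(x) attr(x, "mode")

#' Packaged reference cohort tables
#'
#' The package ships a transcription of a longitudinal reference cohort of 12
#' typically developing infants, each seen at three visits about two months
#' apart and followed to the onset of independent walking (first three
#' unassisted steps). `load_study_tables()` returns the two raw tables:
#' per-visit anthropometrics with Alberta Infant Motor Scale (AIMS) raw
#' scores, and per-visit movement characteristics (daily movement counts per
#' leg, awake hours, movement rates per awake hour, walking-onset age in
#' days). `study_visits()` joins them into one per-visit summary table with
#' the mean-of-legs movement rate used by [fit_onset_model()].
#'
#' @return `load_study_tables()`: a list with tibbles `anthropometrics` (36
#'   rows) and `movement` (36 rows). `study_visits()`: a 36-row tibble with
#'   one row per infant-visit.
#' @examples
#' tabs <- load_study_tables()
#' nrow(tabs$movement)
#' head(study_visits())
#' @export
load_study_tables <- function() {
  read_fixture <- function(name) {
    readr::read_csv(system.file("extdata", name, package = "legmov", mustWork = TRUE),
                    show_col_types = FALSE, progress = FALSE)
  }
  anthro <- read_fixture("study_table1.csv")
  movement <- read_fixture("study_table2.csv")
  stopifnot(nrow(anthro) == 36, nrow(movement) == 36,
            all(movement$awake_hours > 0), all(movement$awake_hours < 24))
  onset_per_infant <- tapply(movement$walking_onset_days, movement$infant,
                             function(x) length(unique(x)))
  stopifnot(all(onset_per_infant == 1))
  list(anthropometrics = anthro, movement = movement)
}

#' @rdname load_study_tables
#' @export
study_visits <- function() {
  tabs <- load_study_tables()
  visits <- left_join(
    tabs$movement,
    select(tabs$anthropometrics, "infant", "visit", "aims_raw", "length_cm"),
    by = c("infant", "visit")
  )
  mutate(visits, rate_mean = (.data$rate_left + .data$rate_right) / 2)
}
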
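#' Score detected movements against observer segment counts
#'
#' Mirrors validation against video observation: within each scored segment
#' the detected count is compared with the observer's count for that leg.
#' Per segment, `over = max(0, detected - observed)` (false positives),
#' `under = max(0, observed - detected)` (false negatives) and
#' `correct = min(detected, observed)`; totals are summed over segments and
#' sensitivity is total correct / total observed. Specificity is undefined
#' in this design: an observer cannot count periods of no movement.
#'
#' @param detected A `movement_events` tibble from [detect_movements()].
#' @param truth An [annotation_set()] in `segment_counts` mode. Segments for
#'   the same leg must not overlap.
#' @return A `validation_report`: a list with totals `n_observed`,
#'   `n_detected`, `n_correct`, `false_positives`, `false_negatives`,
#'   `sensitivity`, the `per_segment` tibble, and `n_unassigned` (detected
#'   events falling outside every segment; excluded from scoring). Use
#'   [tidy()] for the per-segment table and [glance()] for the totals.
#' @examples
#' truth <- annotation_set(data.frame(
#'   segment_start = c(0, 20), segment_end = c(20, 40),
#'   leg = "left", count = c(3, 2)
#' ))
#' det <- structure(
#'   tibble::tibble(leg = "left", start_index = 1:5, end_index = 2:6,
#'                  start_time = c(1, 5, 9, 21, 25) * 1.0,
#'                  end_time = c(2, 6, 10, 22, 26) * 1.0,
#'                  trigger_side = "positive"),
#'   class = c("movement_events", class(tibble::tibble())))
#' score_segments(det, truth)
#' @export
score_segments <- function(detected, truth) {
  stopifnot(inherits(truth, "annotation_set"))
  if (annotation_mode(truth) != "segment_counts") {
    abort("score_segments needs segment_counts annotations",
          class = "legmov_validation_error")
  }
  segs <- as_tibble(truth)
  for (lg in unique(segs$leg)) {
    s <- segs[segs$leg == lg, ]
    s <- s[order(s$segment_start), ]
    if (nrow(s) > 1 &&
        any(utils::head(s$segment_end, -1) > utils::tail(s$segment_start, -1))) {
      abort(paste0("overlapping segments for leg ", lg),
            class = "legmov_validation_error")
    }
  }
  segs$segment <- seq_len(nrow(segs))
  det_count <- function(i) {
    sum(detected$leg == segs$leg[i] &
          detected$start_time >= segs$segment_start[i] &
          detected$start_time < segs$segment_end[i])
  }
  segs$observed <- segs$count
  segs$detected <- vapply(seq_len(nrow(segs)), det_count, integer(1))
  per_segment <- mutate(
    select(segs, "segment", "leg", "segment_start", "segment_end",
           "observed", "detected"),
    over = pmax(0L, .data$detected - .data$observed),
    under = pmax(0L, .data$observed - .data$detected),
    correct = pmin(.data$detected, .data$observed)
  )
  n_assigned <- sum(per_segment$detected)
  new_validation_report(
    n_observed = sum(per_segment$observed),
    n_detected = n_assigned,
    n_correct = sum(per_segment$correct),
    false_positives = sum(per_segment$over),
    false_negatives = sum(per_segment$under),
    per_segment = per_segment,
    mode = "segment_counts",
    n_unassigned = nrow(detected) - n_assigned
  )
}

#' Score detected movements against ground-truth event times
#'
#' A stricter alternative used for simulator output, where individual event
#' onsets are known. Per leg, detected and true events are matched greedily
#' one-to-one in time order when within `tolerance` seconds; matches are
#' correct, unmatched detections are false positives and unmatched truth
#' events are false negatives.
#'
#' @inheritParams score_segments
#' @param truth An [annotation_set()] in `event_times` mode.
#' @param tolerance Matching window in seconds (>= 0).
#' @return A `validation_report` (per-segment table empty).
#' @export
score_events <- function(detected, truth, tolerance = 0.25) {
  stopifnot(inherits(truth, "annotation_set"))
  if (annotation_mode(truth) != "event_times") {
    abort("score_events needs event_times annotations",
          class = "legmov_validation_error")
  }
  if (tolerance < 0) {
    abort("tolerance must be non-negative", class = "legmov_validation_error")
  }
  legs <- union(unique(truth$leg), unique(detected$leg))
  n_correct <- 0L
  n_truth <- 0L
  n_det <- 0L
  for (lg in legs) {
    tt <- sort(truth$time[truth$leg == lg])
    dd <- sort(detected$start_time[detected$leg == lg])
    n_truth <- n_truth + length(tt)
    n_det <- n_det + length(dd)
    i <- 1L
    j <- 1L
    while (i <= length(tt) && j <= length(dd)) {
      if (abs(dd[j] - tt[i]) <= tolerance) {
        n_correct <- n_correct + 1L
        i <- i + 1L
        j <- j + 1L
      } else if (dd[j] < tt[i]) {
        j <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  new_validation_report(
    n_observed = n_truth,
    n_detected = n_det,
    n_correct = n_correct,
    false_positives = n_det - n_correct,
    false_negatives = n_truth - n_correct,
    per_segment = tibble(),
    mode = "event_times",
    n_unassigned = 0L
  )
}

new_validation_report <- function(n_observed, n_detected, n_correct,
                                  false_positives, false_negatives,
                                  per_segment, mode, n_unassigned) {
  structure(
    list(
      n_observed = n_observed,
      n_detected = n_detected,
      n_correct = n_correct,
      false_positives = false_positives,
      false_negatives = false_negatives,
      sensitivity = if (n_observed > 0) n_correct / n_observed else NA_real_,
      per_segment = per_segment,
      mode = mode,
      n_unassigned = n_unassigned
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Movement detector validation (", x$mode, ")\n", sep = "")
  cat("  observed: ", x$n_observed, "   detected: ", x$n_detected, "\n", sep = "")
  cat("  correct: ", x$n_correct,
      "   false positives: ", x$false_positives,
      "   false negatives: ", x$false_negatives, "\n", sep = "")
  cat("  sensitivity: ",
      if (is.na(x$sensitivity)) "NA" else paste0(round(100 * x$sensitivity), "%"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname score_segments
#' @param x A `validation_report`.
#' @param ... Unused.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) as_tibble(x$per_segment)

#' @rdname score_segments
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble(
    n_observed = x$n_observed,
    n_detected = x$n_detected,
    n_correct = x$n_correct,
    false_positives = x$false_positives,
    false_negatives = x$false_negatives,
    sensitivity = x$sensitivity,
    n_unassigned = x$n_unassigned
  )
}

#' Mean movement rate over scored segments
#'
#' Total movements divided by total segment duration, reported to one
#' decimal (movements per second). Accepts either segment-count annotations
#' (counts and durations read off directly) or a `movement_events` tibble
#' plus an explicit segment table.
#'
#' @param x An [annotation_set()] in `segment_counts` mode, or a
#'   `movement_events` tibble.
#' @param segments When `x` is an event tibble: a data frame with
#'   `segment_start`, `segment_end` (s); events are counted by start time.
#' @return Movements per second, rounded to one decimal.
#' @examples
#' truth <- annotation_set(data.frame(
#'   segment_start = 0, segment_end = 460, leg = "left", count = 636
#' ))
#' mean_rate_over_segments(truth) # 1.4
#' @export
mean_rate_over_segments <- function(x, segments = NULL) {
  if (inherits(x, "annotation_set") && annotation_mode(x) == "segment_counts") {
    total <- sum(x$count)
    dur <- sum(x$segment_end - x$segment_start)
  } else {
    if (is.null(segments)) {
      abort("segments must be supplied when scoring an event table",
            class = "legmov_validation_error")
    }
    dur <- sum(segments$segment_end - segments$segment_start)
    total <- sum(vapply(seq_len(nrow(segments)), function(i) {
      sum(x$start_time >= segments$segment_start[i] &
            x$start_time < segments$segment_end[i])
    }, numeric(1)))
  }
  if (dur <= 0) {
    abort("total segment duration must be positive",
          class = "legmov_validation_error")
  }
  round_half_away(total / dur, 1)
}
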
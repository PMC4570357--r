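#' Plot a magnitude series with thresholds and detected movements
#'
#' Draws the detrended acceleration magnitude and the angular-velocity
#' magnitude, the calibrated thresholds as dashed lines, and each detected
#' movement as a segment along the baseline — the standard way to inspect a
#' few seconds of detector behaviour.
#'
#' @param object A `magnitude_series` from [preprocess()].
#' @param thresholds Optional `calibrated_thresholds`.
#' @param events Optional `movement_events`.
#' @param window Optional `c(from, to)` in seconds to zoom into.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot magnitude_series
#' @export
autoplot.magnitude_series <- function(object, thresholds = NULL, events = NULL,
                                      window = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window)) {
    df <- filter(df, .data$t >= window[1], .data$t <= window[2])
    if (!is.null(events)) {
      events <- filter(events, .data$end_time >= window[1],
                       .data$start_time <= window[2])
    }
  }
  long <- tidyr::pivot_longer(df, c("accel_mag", "gyro_mag"),
                              names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                          colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(accel_mag = "#2c6fbb", gyro_mag = "black"),
      labels = c(accel_mag = "acceleration (m/s²)",
                 gyro_mag = "angular velocity (rad/s)")
    ) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(thresholds$pos_threshold, thresholds$neg_threshold),
      linetype = "dashed", colour = "grey30"
    )
  }
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_segment(
      data = events,
      ggplot2::aes(x = .data$start_time, xend = .data$end_time),
      y = 0, yend = 0, colour = "#d14f8e", linewidth = 1.2,
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot per-infant movement-rate trajectories
#'
#' One line per infant of the mean-of-legs movement rate per awake hour
#' across visits, plotted against chronological age (or any other x
#' column, such as months before walking onset).
#'
#' @param visits A visit table such as [study_visits()].
#' @param x Name of the x-axis column.
#' @return A ggplot object.
#' @examples
#' plot_movement_rates(study_visits())
#' @export
plot_movement_rates <- function(visits, x = "age_months") {
  visits <- as_tibble(visits)
  if (!"rate_mean" %in% names(visits)) {
    visits$rate_mean <- (visits$rate_left + visits$rate_right) / 2
  }
  ggplot2::ggplot(visits, ggplot2::aes(x = .data[[x]], y = .data$rate_mean,
                                       group = .data$infant,
                                       colour = .data$infant)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = "movements per awake hour",
                  colour = "infant") +
    ggplot2::theme_minimal()
}

#' @rdname fit_onset_model
#' @param object An `onset_fit`.
#' @method autoplot onset_fit
#' @export
autoplot.onset_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- as.numeric(stats::fitted(object$fit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate_mean)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$walking_onset_days,
                                     shape = .data$.visit_f)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2c6fbb") +
    ggplot2::labs(x = "mean movement rate (movements per awake hour)",
                  y = "walking onset (days)", shape = "visit") +
    ggplot2::theme_minimal()
}
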
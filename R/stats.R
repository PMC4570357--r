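#' Column means and standard deviations of a visit table
#'
#' Reproduces the summary row of a per-visit movement table: per-column mean
#' and sample standard deviation (n - 1 denominator), rounded half away from
#' zero to `digits` decimals (integer reporting by default, matching how
#' daily counts and rates are tabulated).
#'
#' @param visits Data frame of per-infant-per-visit rows.
#' @param columns Character vector of columns to summarize; defaults to all
#'   numeric columns except identifiers (`visit`).
#' @param digits Decimals for the rounded summaries.
#' @return A tibble with columns `variable`, `mean`, `sd`.
#' @examples
#' summarize_visits(study_visits(),
#'                  c("count_left", "count_right", "rate_left", "rate_right"))
#' @export
summarize_visits <- function(visits, columns = NULL, digits = 0) {
  if (nrow(visits) < 2) {
    abort("need at least 2 rows to summarize", class = "legmov_validation_error")
  }
  if (is.null(columns)) {
    numeric_cols <- names(visits)[vapply(visits, is.numeric, logical(1))]
    columns <- setdiff(numeric_cols, "visit")
  }
  tibble(
    variable = columns,
    mean = vapply(columns, function(cl) round_half_away(mean(visits[[cl]]), digits),
                  numeric(1), USE.NAMES = FALSE),
    sd = vapply(columns, function(cl) round_half_away(sd(visits[[cl]]), digits),
                numeric(1), USE.NAMES = FALSE)
  )
}

#' Repeated-measures model of walking onset on movement rate
#'
#' Fits walking-onset age (days at the first three independent steps) on the
#' mean-of-legs movement rate per awake hour, treating visit as a repeated
#' measure with a *diagonal* covariance structure: residuals are independent
#' across rows, but their variance depends on the visit number
#' (heteroscedastic by visit, no within-infant correlation and no random
#' effects). Estimation is by restricted maximum likelihood via
#' [nlme::gls()] with a `varIdent` variance function. An optional single
#' covariate (for example `age_months`, `aims_raw`, or a user-supplied
#' length-for-age percentile) can be added; covariates are modelled one at a
#' time. Inference uses Wald t-tests with residual degrees of freedom, read
#' at a significance level of 0.10.
#'
#' The slope is in days per (movement per awake hour): a slope of 0.041
#' means infants producing 1000 more movements per awake hour walked about
#' 41 days later on average (see [interpret_slope()]).
#'
#' @param visits Data frame with columns `walking_onset_days` (constant
#'   within infant), `visit`, and either `rate_mean` or both `rate_left`
#'   and `rate_right`; plus any covariate column used.
#' @param covariate Optional name of one covariate column.
#' @param method `"REML"` (default) or `"ML"`.
#' @param equal_variances Tie the residual variances across visits
#'   (homoscedastic fit, whose coefficients coincide with ordinary least
#'   squares). Default `FALSE`.
#' @return An object of class `onset_fit`; see [tidy()], [glance()],
#'   [visit_variances()] and [interpret_slope()].
#' @examples
#' fit <- fit_onset_model(study_visits())
#' tidy(fit)
#' interpret_slope(fit, 1000)
#' @export
fit_onset_model <- function(visits, covariate = NULL, method = "REML",
                            equal_variances = FALSE) {
  visits <- as_tibble(visits)
  if (!"rate_mean" %in% names(visits)) {
    if (!all(c("rate_left", "rate_right") %in% names(visits))) {
      abort("visits needs rate_mean or both rate_left and rate_right",
            class = "legmov_validation_error")
    }
    visits$rate_mean <- (visits$rate_left + visits$rate_right) / 2
  }
  required <- c("walking_onset_days", "visit", "rate_mean")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "legmov_validation_error")
  }
  if (!is.null(covariate)) {
    if (!covariate %in% names(visits)) {
      abort(paste0("covariate column not found: ", covariate),
            class = "legmov_validation_error")
    }
    if (anyNA(visits[[covariate]])) {
      abort(paste0("covariate has missing values: ", covariate),
            class = "legmov_validation_error")
    }
  }
  visits$.visit_f <- factor(visits$visit)
  rhs <- paste(c("rate_mean", covariate), collapse = " + ")
  form <- stats::as.formula(paste("walking_onset_days ~", rhs))
  degenerate <- sd(visits$walking_onset_days) == 0
  fit <- if (degenerate) {
    # constant outcome: variance components are 0 and the GLS problem is
    # singular; the coefficients are trivially intercept = outcome, slope 0
    stats::lm(form, data = visits)
  } else if (equal_variances) {
    nlme::gls(form, data = visits, method = method,
              control = nlme::glsControl(tolerance = 1e-10, msTol = 1e-10))
  } else {
    nlme::gls(
      form,
      data = visits,
      weights = nlme::varIdent(form = ~ 1 | .visit_f),
      method = method,
      control = nlme::glsControl(tolerance = 1e-10, msTol = 1e-10)
    )
  }
  structure(
    list(fit = fit, data = visits, covariate = covariate, method = method,
         formula = form, degenerate = degenerate,
         equal_variances = equal_variances),
    class = "onset_fit"
  )
}

#' @export
print.onset_fit <- function(x, ...) {
  cat("Walking-onset repeated-measures model (", x$method,
      if (x$equal_variances) ", tied residual variances" else
        ", visit-specific residual variances",
      ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  tt <- tidy(x)
  row <- tt[tt$term == "rate_mean", ]
  cat("  movement-rate slope: ", signif(row$estimate, 3),
      " days per movement/h (p = ", signif(row$p.value, 2),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_onset_model
#' @param x An `onset_fit`.
#' @param ... Unused.
#' @method tidy onset_fit
#' @export
tidy.onset_fit <- function(x, ...) {
  tt <- if (inherits(x$fit, "gls")) {
    summary(x$fit)$tTable
  } else {
    # degenerate (zero-variance) fits trip summary.lm's perfect-fit warning
    suppressWarnings(stats::coef(summary(x$fit)))
  }
  tibble(
    term = rownames(tt),
    estimate = unname(tt[, 1]),
    std.error = unname(tt[, 2]),
    statistic = unname(tt[, 3]),
    p.value = unname(tt[, 4])
  )
}

#' @rdname fit_onset_model
#' @method glance onset_fit
#' @export
glance.onset_fit <- function(x, ...) {
  f <- x$fit
  tibble(
    n = nrow(x$data),
    logLik = as.numeric(stats::logLik(f)),
    AIC = stats::AIC(f),
    BIC = stats::BIC(f),
    sigma = if (inherits(f, "gls")) f$sigma else summary(f)$sigma,
    method = x$method
  )
}

#' @rdname fit_onset_model
#' @export
visit_variances <- function(x) {
  stopifnot(inherits(x, "onset_fit"))
  lev <- levels(x$data$.visit_f)
  if (x$degenerate) {
    return(stats::setNames(rep(0, length(lev)), paste0("visit_", lev)))
  }
  if (x$equal_variances) {
    return(stats::setNames(rep(x$fit$sigma^2, length(lev)),
                           paste0("visit_", lev)))
  }
  vs <- x$fit$modelStruct$varStruct
  w <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
  out <- (x$fit$sigma * w)^2
  names(out) <- paste0("visit_", names(w))
  out
}

#' Interpret the movement-rate slope as days per rate increment
#'
#' Multiplies the fitted slope (days per movement/h) by a rate increment and
#' rounds to the nearest day: with the default `delta = 1000`, a slope of
#' 0.041 reads as "41 days later per 1000 extra movements per awake hour".
#'
#' @param fit An `onset_fit` from [fit_onset_model()].
#' @param delta Rate increment, movements per awake hour.
#' @return Days, rounded to the nearest integer.
#' @export
interpret_slope <- function(fit, delta = 1000) {
  stopifnot(inherits(fit, "onset_fit"))
  slope <- coef(fit$fit)[["rate_mean"]]
  round_half_away(delta * slope)
}
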
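#' Time within a tolerance band around target
#'
#' The headline performance metric: each present 1 Hz sample accounts for one
#' second; a sample is outside when `|temp - target| > tolerance`. The
#' within-percentage is `100 * within / total`, reported half-up to two
#' decimals.
#'
#' @param series A [trial_series].
#' @param target Target temperature in degC (defaults to the series
#'   attribute).
#' @param tolerance Band half-width in degC.
#' @param column Temperature column to evaluate (`"temp_c"`, or
#'   `"core_temp_c"` for the true state of synthetic trials).
#' @param settle Initial settling time in seconds excluded from the
#'   evaluation (default 0: whole-trial accounting).
#' @return A list with `total_seconds`, `outside_seconds` and
#'   `within_percent`.
#' @examples
#' # arithmetic of the within-percentage
#' tr <- trial_series(0:9, c(rep(38, 8), 39, 39), rep("c38", 10), rep("slow", 10))
#' within_range_fraction(tr, target = 38, tolerance = 0.5)
#' @export
within_range_fraction <- function(series, target = attr(series, "target_temp"),
                                  tolerance, column = "temp_c", settle = 0) {
  stopifnot(inherits(series, "trial_series"), is_scalar_number(tolerance),
            tolerance > 0, is_scalar_number(settle), settle >= 0)
  if (!is_scalar_number(target)) {
    ttm_error("no target temperature given and none stored in the series",
              "ttm_invalid_config")
  }
  temps <- series[[column]]
  if (is.null(temps)) {
    ttm_error(sprintf("series has no column '%s'", column), "ttm_load_error")
  }
  if (settle > 0) {
    temps <- temps[series$time_s >= series$time_s[1] + settle]
  }
  total <- length(temps)
  if (total == 0L) ttm_error("no samples to evaluate", "ttm_empty_series")
  outside <- sum(abs(temps - target) > tolerance)
  list(total_seconds = total,
       outside_seconds = outside,
       within_percent = round_half_up(100 * (total - outside) / total, 2))
}

#' Count device-setting adaptions
#'
#' Number of rows at which the recorded `(heat, speed)` tuple differs from
#' the previous row, and the rate per hour of recording (total duration =
#' number of present 1 Hz samples), reported half-up to two decimals.
#'
#' @param series A [trial_series].
#' @param settle Initial settling time in seconds excluded (default 0).
#' @return A list with `n_changes`, `total_seconds` and `changes_per_hour`.
#' @export
count_setting_changes <- function(series, settle = 0) {
  stopifnot(inherits(series, "trial_series"))
  keep <- series$time_s >= series$time_s[1] + settle
  heat <- series$heat[keep]
  speed <- series$speed[keep]
  total <- length(heat)
  if (total == 0L) ttm_error("no samples to evaluate", "ttm_empty_series")
  changed <- heat[-1] != heat[-total] | speed[-1] != speed[-total]
  n <- sum(changed)
  list(n_changes = n,
       total_seconds = total,
       changes_per_hour = round_half_up(n / (total / 3600), 2))
}

#' Sliding-window median filter
#'
#' Centered running median over the samples within `window/2` seconds of each
#' time point, used to filter short measurement interruptions (flushes, cold
#' infusions) for display. Edges use the available partial window.
#'
#' @param series A [trial_series] (or a numeric vector, with `time` supplied).
#' @param window Window width in seconds (>= 1; the study figures use 120).
#' @param time Sample times; defaults to the series' `time_s`.
#' @return Numeric vector of filtered temperatures, same length as the input.
#' @export
sliding_median <- function(series, window = 120, time = NULL) {
  if (inherits(series, "trial_series")) {
    x <- series$temp_c
    time <- series$time_s
  } else {
    x <- as.numeric(series)
    if (is.null(time)) time <- seq_along(x) - 1
  }
  stopifnot(is_scalar_number(window), window >= 1, length(time) == length(x))
  n <- length(x)
  half <- window / 2
  out <- numeric(n)
  lo <- 1L
  hi <- 0L
  for (i in seq_len(n)) {
    while (time[lo] < time[i] - half) lo <- lo + 1L
    while (hi < n && time[hi + 1L] <= time[i] + half) hi <- hi + 1L
    out[i] <- stats::median.default(x[lo:hi])
  }
  out
}

#' Performance report for a trial
#'
#' Bundles the time-in-range metrics at several tolerances with the
#' setting-adaption counts — the per-trial summary the evaluation tables
#' report.
#'
#' @param series A [trial_series].
#' @param target Target temperature in degC.
#' @param tolerances Band half-widths in degC (default 0.5 and 1.0).
#' @param settle Initial settling time in seconds excluded (default 0:
#'   whole-trial accounting, as in the recorded evaluations).
#' @param filtered If `TRUE`, metrics are computed on the 120 s
#'   sliding-median-filtered temperature instead of raw readings
#'   (sensitivity analysis; the recorded tables use raw 1 Hz readings).
#' @param column Temperature column to evaluate.
#' @return An object of class `performance_report`.
#' @export
performance_report <- function(series, target = attr(series, "target_temp"),
                               tolerances = c(0.5, 1.0), settle = 0,
                               filtered = FALSE, column = "temp_c") {
  stopifnot(inherits(series, "trial_series"), length(tolerances) >= 1)
  if (filtered) {
    series[[column]] <- sliding_median(series[[column]], window = 120,
                                       time = series$time_s)
  }
  bands <- lapply(tolerances, function(tol) {
    within_range_fraction(series, target = target, tolerance = tol,
                          column = column, settle = settle)
  })
  names(bands) <- sprintf("tol_%s", format(tolerances))
  ch <- count_setting_changes(series, settle = settle)
  structure(list(
    label = attr(series, "label"),
    target_temp = target,
    settle_seconds = settle,
    filtered = filtered,
    column = column,
    total_seconds = bands[[1]]$total_seconds,
    tolerances = tolerances,
    bands = bands,
    n_changes = ch$n_changes,
    changes_per_hour = ch$changes_per_hour
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> trial '%s' | target %.1f °C | %d s evaluated\n",
              x$label, x$target_temp, x$total_seconds))
  if (x$settle_seconds > 0) {
    cat(sprintf("  (first %g s excluded as settling)\n", x$settle_seconds))
  }
  if (x$filtered) cat("  (120 s sliding-median filtered)\n")
  for (i in seq_along(x$tolerances)) {
    b <- x$bands[[i]]
    cat(sprintf("  within ±%.1f °C : %7.2f %%  (outside %d s)\n",
                x$tolerances[i], b$within_percent, b$outside_seconds))
  }
  cat(sprintf("  setting changes: %d (%.2f per hour)\n",
              x$n_changes, x$changes_per_hour))
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(
    label = x$label,
    target_temp_c = x$target_temp,
    tolerance_c = x$tolerances,
    total_s = x$total_seconds,
    outside_s = vapply(x$bands, function(b) b$outside_seconds, 0),
    within_percent = vapply(x$bands, function(b) b$within_percent, 0),
    n_changes = x$n_changes,
    changes_per_hour = x$changes_per_hour,
    row.names = NULL
  )
}
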
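#' Controller configuration
#'
#' The annealing temperature controller has three tunable parameters: the
#' target temperature, the evaluation interval over which raw 1 Hz readings
#' are averaged before each adaption, and a scaling factor that converts the
#' averaged temperature error into a step of the control state. The study
#' configuration is the default: target 38.0 degC, 120 s interval, scaling
#' 0.7.
#'
#' Two update modes are provided. In `integral` mode (default) the scaled
#' error is accumulated into the saturating state, so the controller anneals
#' towards the extreme settings in several steps and backs off as soon as the
#' error reverses sign. In `proportional` mode the state is the scaled error
#' itself; it is included for comparison and gives up the annealing memory.
#'
#' @param target_temp Target core temperature in degC, within \[30, 42\].
#' @param eval_interval Evaluation/averaging interval in seconds (>= 1).
#' @param scaling_factor Positive gain applied to the temperature error
#'   (1/degC, i.e. state units per degC of error).
#' @param mode `"integral"` or `"proportional"`.
#' @return An object of class `controller_config`.
#' @examples
#' controller_config()  # the study parameters
#' @export
controller_config <- function(target_temp = 38.0, eval_interval = 120L,
                              scaling_factor = 0.7,
                              mode = c("integral", "proportional")) {
  mode <- match.arg(mode)
  if (!is_scalar_number(target_temp) || target_temp < 30 || target_temp > 42) {
    ttm_error("target_temp must lie within [30, 42] degC", "ttm_invalid_config")
  }
  if (!is_scalar_number(eval_interval) || eval_interval < 1 ||
      eval_interval != round(eval_interval)) {
    ttm_error("eval_interval must be a positive integer number of seconds",
              "ttm_invalid_config")
  }
  if (!is_scalar_number(scaling_factor) || scaling_factor <= 0) {
    ttm_error("scaling_factor must be > 0", "ttm_invalid_config")
  }
  structure(list(target_temp = target_temp,
                 eval_interval = as.integer(eval_interval),
                 scaling_factor = scaling_factor,
                 mode = mode),
            class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf("<controller_config> target %.1f °C | interval %d s | scaling %.3g | %s\n",
              x$target_temp, x$eval_interval, x$scaling_factor, x$mode))
  invisible(x)
}

#' Read a controller configuration from a flat key-value file
#'
#' Accepts `key = value` (or `key: value`) lines; recognized keys are
#' `target_temp_c`, `eval_interval_s`, `scaling_factor` and `mode`. Missing
#' keys fall back to the study defaults.
#'
#' @param path File path.
#' @return A [controller_config].
#' @export
read_controller_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_.]+)\\s*[=:]\\s*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  vals <- stats::setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
  controller_config(
    target_temp = as.numeric(vals["target_temp_c"] %|na|% 38.0),
    eval_interval = as.numeric(vals["eval_interval_s"] %|na|% 120),
    scaling_factor = as.numeric(vals["scaling_factor"] %|na|% 0.7),
    mode = as.character(vals["mode"] %|na|% "integral")
  )
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else unname(a)

#' A single temperature reading
#'
#' One 1 Hz sample from the patient monitor: seconds since trial start, a
#' blood temperature, and a validity flag (invalid marks a missing or
#' pre-flagged reading; transient artifacts such as catheter flushes arrive
#' as *valid* readings and are absorbed by the averaging window).
#'
#' @param time Seconds since trial start (non-negative).
#' @param temp Temperature in degC; must lie within \[15, 45\] when valid.
#' @param valid Logical.
#' @return An object of class `temperature_sample`.
#' @export
temperature_sample <- function(time, temp, valid = TRUE) {
  stopifnot(is_scalar_number(time), length(valid) == 1L, is.logical(valid))
  if (valid && (!is_scalar_number(temp) || temp < 15 || temp > 45)) {
    ttm_error(sprintf("valid temperature %.3f degC outside plausible range [15, 45]",
                      temp), "ttm_invalid_sample")
  }
  structure(list(time = time, temp = temp, valid = isTRUE(valid)),
            class = "temperature_sample")
}

#' Controller state
#'
#' The running state of the closed loop: the saturating control state `s` in
#' \[-1, 1\] (initially 0, the neutral starting point; -1 means maximal
#' cooling, +1 maximal heating), the buffer of samples collected since the
#' last evaluation, the last commanded setting and the time of the last
#' evaluation.
#'
#' @param time0 Trial start time in seconds; the first evaluation fires one
#'   full interval after it.
#' @param setting Setting assumed active before the first evaluation
#'   (defaults to the neutral `state_to_setting(0)`).
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(time0 = 0, setting = state_to_setting(0)) {
  stopifnot(is_scalar_number(time0), inherits(setting, "device_setting"))
  structure(list(
    s = 0,
    window = list(time = numeric(0), temp = numeric(0), valid = logical(0)),
    last_setting = setting,
    last_eval_time = time0,
    last_time = time0
  ), class = "controller_state")
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf("<controller_state> s = %.4f | window n = %d | last eval t = %g | last setting %s\n",
              x$s, length(x$window$time), x$last_eval_time,
              format(x$last_setting)))
  invisible(x)
}

#' Windowed mean temperature
#'
#' Arithmetic mean of the valid samples in the current evaluation window.
#' Raw monitor readings are noisy and occasionally corrupted by flush or
#' cold-injection transients; averaging over the window is the controller's
#' only artifact defense.
#'
#' @param window A list or data frame with elements `temp` and `valid`.
#' @return Mean temperature in degC of the valid samples.
#' @section Errors: signals a condition of class `ttm_no_data` when no valid
#'   sample is present (the caller then retains the previous setting).
#' @export
window_mean <- function(window) {
  keep <- window$valid
  if (!any(keep)) {
    ttm_error("no valid sample in evaluation window", "ttm_no_data")
  }
  mean(window$temp[keep])
}

#' Temperature error
#'
#' `target_temp - mean_temp`: positive when the subject is too cold (heating
#' needed), negative when too warm — the negative-feedback convention under
#' which state +1 means maximal heating.
#'
#' @param mean_temp Windowed mean temperature in degC.
#' @param target_temp Target temperature in degC.
#' @return Error in degC.
#' @export
compute_error <- function(mean_temp, target_temp) {
  stopifnot(is_scalar_number(mean_temp), is_scalar_number(target_temp))
  target_temp - mean_temp
}

#' Update the saturating control state
#'
#' In integral mode the scaled error is added to the previous state; in
#' proportional mode it replaces it. Either way the result is clamped to
#' \[-1, 1\], so the state saturates at the maximal-cooling/heating ends and
#' can always back off within a few evaluations.
#'
#' @param s_prev Previous state in \[-1, 1\].
#' @param error Temperature error in degC (target minus mean).
#' @param scaling_factor Positive gain.
#' @param mode `"integral"` or `"proportional"`.
#' @return New state in \[-1, 1\].
#' @examples
#' update_state(0.9, 0.5, 0.7, "integral")  # saturates at 1
#' @export
update_state <- function(s_prev, error, scaling_factor,
                         mode = c("integral", "proportional")) {
  mode <- match.arg(mode)
  stopifnot(is_scalar_number(s_prev), is_scalar_number(error),
            is_scalar_number(scaling_factor))
  if (s_prev < -1 || s_prev > 1) {
    ttm_error("s_prev outside [-1, 1]", "ttm_contract_violation")
  }
  raw <- if (mode == "integral") s_prev + error * scaling_factor
         else error * scaling_factor
  clamp(raw, -1, 1)
}

#' Map the control state to a device setting
#'
#' Quantizes the continuous state into the six usable actuator settings.
#' The intervals are upper-inclusive; the endpoints map to the extreme
#' settings where the fast blower is engaged. `standby` is never returned
#' (it would deflate the blanket).
#'
#' \preformatted{
#'   s = -1            -> (ambient 21 degC, fast)   maximal cooling
#'   -1  < s <= -0.5   -> (ambient 21 degC, slow)
#'   -0.5 < s <=  0    -> (32 degC, slow)
#'    0  < s <=  0.5   -> (38 degC, slow)
#'   0.5 < s <   1     -> (43 degC, slow)
#'   s =  1            -> (43 degC, fast)           maximal heating
#' }
#'
#' @param s Control state in \[-1, 1\].
#' @return A [device_setting].
#' @export
state_to_setting <- function(s) {
  stopifnot(is_scalar_number(s))
  if (s < -1 || s > 1) {
    ttm_error(sprintf("control state %g outside [-1, 1]", s),
              "ttm_contract_violation")
  }
  if (s == -1) {
    device_setting("ambient21", "fast")
  } else if (s <= -0.5) {
    device_setting("ambient21", "slow")
  } else if (s <= 0) {
    device_setting("c32", "slow")
  } else if (s <= 0.5) {
    device_setting("c38", "slow")
  } else if (s < 1) {
    device_setting("c43", "slow")
  } else {
    device_setting("c43", "fast")
  }
}

#' Advance the controller by one sample
#'
#' Appends the sample to the evaluation window. When a full evaluation
#' interval has elapsed since the last evaluation, the controller averages
#' the valid window samples (restricted to the trailing `eval_interval`
#' seconds), computes the error, updates the saturating state, maps it to a
#' setting, clears the window and returns the setting — returned even when
#' unchanged; the caller deduplicates before actuating. Between evaluations
#' (or when the window holds no valid sample at evaluation time) no setting
#' is returned and the previous setting stays in force.
#'
#' @param state A [controller_state].
#' @param config A [controller_config].
#' @param sample A [temperature_sample]; samples must arrive in
#'   non-decreasing time order.
#' @return A list with elements `state` (the new [controller_state]) and
#'   `setting` (a [device_setting], or `NULL` when no evaluation fired or
#'   the window was empty).
#' @export
controller_step <- function(state, config, sample) {
  stopifnot(inherits(state, "controller_state"),
            inherits(config, "controller_config"),
            inherits(sample, "temperature_sample"))
  if (sample$time < state$last_time) {
    ttm_error(sprintf("out-of-order sample: time %g before %g",
                      sample$time, state$last_time),
              "ttm_out_of_order")
  }
  state$last_time <- sample$time
  state$window$time <- c(state$window$time, sample$time)
  state$window$temp <- c(state$window$temp, sample$temp)
  state$window$valid <- c(state$window$valid, sample$valid)

  if (sample$time - state$last_eval_time < config$eval_interval) {
    return(list(state = state, setting = NULL))
  }

  # evaluation instant: use valid samples within the trailing interval
  keep <- state$window$valid &
    state$window$time > sample$time - config$eval_interval
  setting <- NULL
  if (any(keep)) {
    mbar <- mean(state$window$temp[keep])
    e <- compute_error(mbar, config$target_temp)
    state$s <- update_state(state$s, e, config$scaling_factor, config$mode)
    setting <- state_to_setting(state$s)
    state$last_setting <- setting
  }
  state$window <- list(time = numeric(0), temp = numeric(0), valid = logical(0))
  state$last_eval_time <- sample$time
  list(state = state, setting = setting)
}

#' Run the controller over a full sample stream
#'
#' Equivalent to folding [controller_step()] over the stream (a property the
#' test suite asserts), but implemented over evaluation boundaries so long
#' 1 Hz trials replay quickly. Returns one row per evaluation instant.
#'
#' @param time Numeric vector of sample times (seconds, non-decreasing).
#' @param temp Numeric vector of temperatures (degC).
#' @param valid Logical vector (default all valid).
#' @param config A [controller_config].
#' @param time0 Trial start time (default `time[1]`); the first evaluation
#'   fires once `eval_interval` seconds have elapsed after it.
#' @param init_setting Setting active before the first evaluation.
#' @return A list with `evaluations` (data frame: `time`, `mean_temp`,
#'   `error`, `s`, `heat`, `speed`, `has_data`) and `state` (final
#'   [controller_state]). Evaluations with an all-invalid window carry the
#'   retained previous setting and `has_data = FALSE`.
#' @export
run_controller <- function(time, temp, valid = rep(TRUE, length(time)),
                           config = controller_config(),
                           time0 = if (length(time)) time[1] else 0,
                           init_setting = state_to_setting(0)) {
  stopifnot(inherits(config, "controller_config"),
            length(time) == length(temp), length(time) == length(valid))
  if (is.unsorted(time)) {
    ttm_error("sample times must be non-decreasing", "ttm_out_of_order")
  }
  n <- length(time)
  ct <- config$eval_interval
  cs <- config$scaling_factor
  tar <- config$target_temp
  integral <- config$mode == "integral"

  cap <- max(16L, n %/% max(ct, 1L) + 2L)
  ev_time <- numeric(cap); ev_mean <- numeric(cap); ev_err <- numeric(cap)
  ev_s <- numeric(cap); ev_heat <- character(cap); ev_speed <- character(cap)
  ev_data <- logical(cap)

  s <- 0
  last_eval <- time0
  setting <- init_setting
  seg_start <- 1L   # first index of the current (cleared) window
  m <- 0L
  repeat {
    # first sample at which a full interval has elapsed:
    # left.open counts elements strictly below the threshold
    j <- findInterval(last_eval + ct, time, left.open = TRUE) + 1L
    if (j < seg_start) j <- seg_start
    if (j > n) break
    idx <- seg_start:j
    keep <- valid[idx] & time[idx] > time[j] - ct
    m <- m + 1L
    ev_time[m] <- time[j]
    if (any(keep)) {
      mbar <- mean(temp[idx][keep])
      e <- tar - mbar
      s <- clamp(if (integral) s + e * cs else e * cs, -1, 1)
      setting <- state_to_setting(s)
      ev_mean[m] <- mbar; ev_err[m] <- e; ev_data[m] <- TRUE
    } else {
      ev_mean[m] <- NA_real_; ev_err[m] <- NA_real_; ev_data[m] <- FALSE
    }
    ev_s[m] <- s
    ev_heat[m] <- setting$heat
    ev_speed[m] <- setting$speed
    last_eval <- time[j]
    seg_start <- j + 1L
    if (seg_start > n) break
  }

  final <- controller_state(time0 = time0, setting = init_setting)
  final$s <- s
  final$last_setting <- setting
  final$last_eval_time <- last_eval
  final$last_time <- if (n) time[n] else time0
  if (seg_start <= n) {
    idx <- seg_start:n
    final$window <- list(time = time[idx], temp = temp[idx], valid = valid[idx])
  }

  list(
    evaluations = data.frame(
      time = ev_time[seq_len(m)],
      mean_temp = ev_mean[seq_len(m)],
      error = ev_err[seq_len(m)],
      s = ev_s[seq_len(m)],
      heat = ev_heat[seq_len(m)],
      speed = ev_speed[seq_len(m)],
      has_data = ev_data[seq_len(m)],
      stringsAsFactors = FALSE
    ),
    state = final
  )
}
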
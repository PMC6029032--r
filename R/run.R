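#' Read a run configuration file
#'
#' YAML file with optional top-level sections `controller:` and `plant:`
#' (keys as the arguments of [controller_config()] and [plant_config()]),
#' plus run-level keys `duration`, `seed`, `settle`, `label`, `tolerances`.
#' Unknown keys are rejected so typos surface as errors.
#'
#' @param path YAML file path.
#' @return A list with elements `controller` ([controller_config]),
#'   `plant` ([plant_config]), `duration`, `seed`, `settle`, `label` and
#'   `tolerances`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ttm_error(sprintf("no such file: %s", path), "ttm_load_error")
  raw <- yaml::read_yaml(path)
  known <- c("controller", "plant", "duration", "seed", "settle", "label",
             "tolerances")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    ttm_error(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
              "ttm_invalid_config")
  }
  ctl <- raw$controller %||% list()
  bad <- setdiff(names(ctl), names(formals(controller_config)))
  if (length(bad)) {
    ttm_error(sprintf("unknown controller keys: %s", paste(bad, collapse = ", ")),
              "ttm_invalid_config")
  }
  pl <- raw$plant %||% list()
  pl_known <- setdiff(names(formals(plant_config)), "fever_profile")
  bad <- setdiff(names(pl), c(pl_known, "fever_onset", "fever_ramp", "fever_peak"))
  if (length(bad)) {
    ttm_error(sprintf("unknown plant keys: %s", paste(bad, collapse = ", ")),
              "ttm_invalid_config")
  }
  fev <- fever_ramp(onset = pl$fever_onset %||% 4 * 3600,
                    ramp = pl$fever_ramp %||% 8 * 3600,
                    peak = pl$fever_peak %||% 15)
  pl <- pl[intersect(names(pl), pl_known)]
  pl$fever_profile <- fev
  list(
    controller = do.call(controller_config, ctl),
    plant = do.call(plant_config, pl),
    duration = raw$duration %||% 324000,
    seed = raw$seed %||% 1L,
    settle = raw$settle %||% 7200,
    label = raw$label %||% "run",
    tolerances = raw$tolerances %||% c(0.5, 1.0)
  )
}

#' Simulate a closed-loop trial and evaluate it
#'
#' Runs the full loop — plant, controller, device emulator — for `duration`
#' seconds at 1 Hz, optionally writes the trial CSV and a report, and returns
#' both. Deterministic for a fixed seed.
#'
#' @param plant A [plant_config].
#' @param controller A [controller_config].
#' @param duration Trial length in seconds (default 90 h).
#' @param seed Integer seed for the measurement noise stream.
#' @param settle Settling time in seconds excluded from the report (default
#'   2 h; set 0 for whole-trial accounting as in the recorded evaluations).
#' @param tolerances Report band half-widths in degC.
#' @param label Trial label.
#' @param out_csv,out_report Optional output paths (trial CSV / report CSV).
#' @return A list with `series` ([trial_series]) and `report`
#'   ([performance_report], computed on the true core temperature).
#' @export
run_simulate <- function(plant = plant_config(), controller = controller_config(),
                         duration = 324000, seed = plant$seed, settle = 7200,
                         tolerances = c(0.5, 1.0), label = "simulated",
                         out_csv = NULL, out_report = NULL) {
  series <- generate_trial(plant, controller = controller, duration = duration,
                           seed = seed, label = label)
  report <- performance_report(series, target = controller$target_temp,
                               tolerances = tolerances, settle = settle,
                               column = "core_temp_c")
  if (!is.null(out_csv)) write_trial_csv(series, out_csv)
  if (!is.null(out_report)) {
    utils::write.csv(as.data.frame(report), out_report, row.names = FALSE)
  }
  list(series = series, report = report)
}

#' Generate an open-loop (uncontrolled) trial
#'
#' @inheritParams run_simulate
#' @param setting Constant [device_setting] held for the whole trial
#'   (default: no blanket).
#' @param out_csv Optional output path.
#' @return A [trial_series].
#' @export
run_generate <- function(plant = plant_config(), duration = 324000,
                         seed = plant$seed,
                         setting = device_setting("ambient21", "standby"),
                         label = "uncontrolled", out_csv = NULL) {
  series <- generate_trial(plant, controller = NULL, duration = duration,
                           seed = seed, open_loop_setting = setting,
                           label = label)
  if (!is.null(out_csv)) write_trial_csv(series, out_csv)
  series
}

#' Evaluate a recorded trial
#'
#' @param input A [trial_series], or the path of a trial CSV.
#' @param target Target temperature in degC (defaults to the series
#'   metadata).
#' @param tolerances Band half-widths in degC.
#' @param settle Settling exclusion in seconds (default 0).
#' @param filtered Compute on 120 s sliding-median-filtered readings.
#' @param column Temperature column to evaluate.
#' @param column_map Passed to [read_trial_csv()] when `input` is a path.
#' @param out_report Optional report CSV path.
#' @return A [performance_report].
#' @export
run_evaluate <- function(input, target = NULL, tolerances = c(0.5, 1.0),
                         settle = 0, filtered = FALSE, column = "temp_c",
                         column_map = NULL, out_report = NULL) {
  series <- if (inherits(input, "trial_series")) input
            else do.call(read_trial_csv,
                         c(list(path = input),
                           if (is.null(column_map)) NULL
                           else list(column_map = column_map)))
  report <- performance_report(
    series,
    target = target %||% attr(series, "target_temp"),
    tolerances = tolerances, settle = settle,
    filtered = filtered, column = column)
  if (!is.null(out_report)) {
    utils::write.csv(as.data.frame(report), out_report, row.names = FALSE)
  }
  report
}

#' Replay the controller over a recorded trial
#'
#' @inheritParams run_evaluate
#' @param controller A [controller_config] (the trial's study parameters).
#' @return A [replay_report].
#' @export
run_replay <- function(input, controller = controller_config(),
                       column_map = NULL) {
  series <- if (inherits(input, "trial_series")) input
            else do.call(read_trial_csv,
                         c(list(path = input),
                           if (is.null(column_map)) NULL
                           else list(column_map = column_map)))
  replay_controller(series, config = controller)
}
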
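#' Replay the controller against a recorded trial
#'
#' Feeds the recorded temperatures through the control algorithm and compares
#' the settings it would have commanded with the settings actually recorded —
#' the consistency oracle for automated trials. For a trial generated by this
#' package and replayed with the same configuration the agreement is exact.
#'
#' A recorded row at time `t` is compared against the predicted setting in
#' force at `t`: the setting emitted by the evaluation at `t` itself when one
#' fired there, else the latest earlier one (the first recorded setting
#' before any evaluation).
#'
#' @param series A [trial_series].
#' @param config A [controller_config]; use the trial's study parameters.
#' @param init_setting Setting assumed before the first evaluation (default:
#'   the first recorded row's setting).
#' @return An object of class `replay_report`: per-evaluation predictions
#'   (`evaluations`), the per-second predicted `heat`/`speed`, the fraction
#'   and percentage of seconds in agreement with the recording, and predicted
#'   vs recorded change counts.
#' @export
replay_controller <- function(series, config = controller_config(),
                              init_setting = device_setting(series$heat[1],
                                                            series$speed[1])) {
  stopifnot(inherits(series, "trial_series"),
            inherits(config, "controller_config"))
  res <- run_controller(series$time_s, series$temp_c,
                        config = config, init_setting = init_setting)
  ev <- res$evaluations

  # expand evaluation instants to a per-second step function
  idx <- findInterval(series$time_s, ev$time)   # 0 before the first evaluation
  pred_heat <- c(init_setting$heat, ev$heat)[idx + 1L]
  pred_speed <- c(init_setting$speed, ev$speed)[idx + 1L]

  agree <- pred_heat == series$heat & pred_speed == series$speed
  n <- nrow(series)
  pred_changes <- if (n > 1L) {
    sum(pred_heat[-1] != pred_heat[-n] | pred_speed[-1] != pred_speed[-n])
  } else 0L
  rec_changes <- count_setting_changes(series)$n_changes

  structure(list(
    label = attr(series, "label"),
    config = config,
    evaluations = ev,
    predicted = data.frame(time_s = series$time_s, heat = pred_heat,
                           speed = pred_speed, stringsAsFactors = FALSE),
    agreement_fraction = mean(agree),
    agreement_percent = round_half_up(100 * mean(agree), 2),
    n_changes_predicted = pred_changes,
    n_changes_recorded = rec_changes
  ), class = "replay_report")
}

#' @export
print.replay_report <- function(x, ...) {
  cat(sprintf("<replay_report> trial '%s' | %d evaluations\n",
              x$label, nrow(x$evaluations)))
  cat(sprintf("  setting agreement: %.2f %% of recorded seconds\n",
              x$agreement_percent))
  cat(sprintf("  setting changes: predicted %d, recorded %d\n",
              x$n_changes_predicted, x$n_changes_recorded))
  invisible(x)
}
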
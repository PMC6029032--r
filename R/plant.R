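#' Fever power profile
#'
#' Prolonged narcosis in the emulated subject commonly produces a slow
#' medication-associated fever. It is modeled as extra metabolic power that
#' ramps linearly from zero at `onset` to `peak` over `ramp` seconds and
#' then holds.
#'
#' @param onset Seconds until the fever starts (default 4 h).
#' @param ramp Ramp duration in seconds (default 8 h).
#' @param peak Added power at plateau in W (default 15).
#' @return A vectorized function `f(t)` returning added power in W.
#' @export
fever_ramp <- function(onset = 4 * 3600, ramp = 8 * 3600, peak = 15) {
  stopifnot(is_scalar_number(onset), is_scalar_number(ramp), ramp > 0,
            is_scalar_number(peak))
  function(t) peak * pmin(1, pmax(0, (t - onset) / ramp))
}

#' Plant configuration: lumped thermal model of the subject
#'
#' Single-compartment heat balance of an anesthetized ~40-45 kg subject under
#' a forced-air blanket:
#'
#' \preformatted{
#'   C dT/dt = P_met(t) - k_ambient (T - T_amb) - k_blanket(speed) (T - T_air)
#' }
#'
#' with heat capacity `C = mass * specific_heat`, a passive loss path to room
#' air and a convective exchange path through the blanket whose coefficient
#' depends on the blower speed (zero in standby: the blanket is deflated).
#' Metabolic power is basal plus a fever profile. The defaults emulate the
#' study conditions: a 42 kg subject whose uncontrolled temperature drifts
#' febrile (above 39.5 degC within about a day), while maximal cooling
#' (ambient air, fast blower) can always pull it back below 38 degC, and no
#' single quantized setting balances exactly at 38.0 degC — so the closed
#' loop must alternate between adjacent settings.
#'
#' @param mass Body mass in kg.
#' @param specific_heat Average tissue specific heat in J/(kg K).
#' @param k_ambient Passive loss coefficient to room air in W/K.
#' @param k_blanket_slow,k_blanket_fast Blanket exchange coefficients in W/K
#'   (`fast > slow`; both bounded above by the airflow heat-capacity rate,
#'   about 24 and 28 W/K at 20 and 23 L/s).
#' @param ambient_temp Room temperature in degC.
#' @param basal_metabolic_power Basal metabolic heat in W.
#' @param fever_profile Vectorized function time (s) -> added power (W).
#' @param noise_sd Measurement noise standard deviation in degC.
#' @param artifact_schedule `NULL`, or a data frame with columns `onset` (s),
#'   `duration` (s) and `offset` (degC) describing transient measurement
#'   artifacts (catheter flushes, cold-fluid calibration injections). See
#'   [artifact_schedule()].
#' @param initial_temp Core temperature at trial start in degC. The default
#'   37.5 reflects the mild heat loss accrued during instrumentation.
#' @param seed Integer seed used by [generate_trial()] for the measurement
#'   noise stream.
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(mass = 42, specific_heat = 3500,
                         k_ambient = 5,
                         k_blanket_slow = 18, k_blanket_fast = 25,
                         ambient_temp = 21,
                         basal_metabolic_power = 90,
                         fever_profile = fever_ramp(),
                         noise_sd = 0.05,
                         artifact_schedule = NULL,
                         initial_temp = 37.5,
                         seed = 1L) {
  stopifnot(is_scalar_number(mass), mass > 0,
            is_scalar_number(specific_heat), specific_heat > 0,
            is_scalar_number(k_ambient), k_ambient > 0,
            is_scalar_number(k_blanket_slow), k_blanket_slow > 0,
            is_scalar_number(k_blanket_fast), k_blanket_fast > 0,
            is_scalar_number(ambient_temp),
            is_scalar_number(basal_metabolic_power),
            basal_metabolic_power >= 0,
            is.function(fever_profile),
            is_scalar_number(noise_sd), noise_sd >= 0,
            is_scalar_number(initial_temp),
            initial_temp >= 15, initial_temp <= 45)
  if (k_blanket_fast <= k_blanket_slow) {
    ttm_error("k_blanket_fast must exceed k_blanket_slow", "ttm_invalid_config")
  }
  if (!is.null(artifact_schedule)) {
    stopifnot(is.data.frame(artifact_schedule),
              all(c("onset", "duration", "offset") %in% names(artifact_schedule)))
  }
  structure(list(mass = mass, specific_heat = specific_heat,
                 k_ambient = k_ambient,
                 k_blanket_slow = k_blanket_slow,
                 k_blanket_fast = k_blanket_fast,
                 ambient_temp = ambient_temp,
                 basal_metabolic_power = basal_metabolic_power,
                 fever_profile = fever_profile,
                 noise_sd = noise_sd,
                 artifact_schedule = artifact_schedule,
                 initial_temp = initial_temp,
                 seed = as.integer(seed)),
            class = "plant_config")
}

#' @export
print.plant_config <- function(x, ...) {
  cat(sprintf(paste0("<plant_config> %g kg x %g J/(kg K) | k_amb %g W/K | ",
                     "k_blanket %g/%g W/K | ambient %g °C | basal %g W | ",
                     "noise sd %g °C | T0 %g °C\n"),
              x$mass, x$specific_heat, x$k_ambient,
              x$k_blanket_slow, x$k_blanket_fast, x$ambient_temp,
              x$basal_metabolic_power, x$noise_sd, x$initial_temp))
  invisible(x)
}

#' Build a measurement-artifact schedule
#'
#' Periodic transient offsets on the measured (not the true) temperature,
#' emulating catheter flushes and the cold-fluid injections used to
#' recalibrate cardiac output every few hours.
#'
#' @param duration Trial duration in seconds (events beyond it are dropped).
#' @param first Time of the first event in seconds (default 3 h).
#' @param interval Event spacing in seconds (default 4 h).
#' @param event_duration Event length in seconds (default 30).
#' @param offset Temperature offset in degC during the event (default -2,
#'   a cold-injection dip).
#' @return Data frame with columns `onset`, `duration`, `offset`.
#' @export
artifact_schedule <- function(duration, first = 3 * 3600, interval = 4 * 3600,
                              event_duration = 30, offset = -2) {
  onsets <- seq(first, duration, by = interval)
  onsets <- onsets[onsets < duration]
  data.frame(onset = onsets,
             duration = rep(event_duration, length(onsets)),
             offset = rep(offset, length(onsets)))
}

# total artifact offset active at each time point (vectorized over t)
artifact_offset_at <- function(schedule, t) {
  out <- numeric(length(t))
  if (is.null(schedule) || nrow(schedule) == 0L) return(out)
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset[i]
    act <- t >= on & t < on + schedule$duration[i]
    out[act] <- out[act] + schedule$offset[i]
  }
  out
}

#' Plant state
#'
#' @param time Seconds since trial start.
#' @param core_temp Core temperature in degC, within \[15, 45\].
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(time = 0, core_temp = 37.5) {
  stopifnot(is_scalar_number(time),
            is_scalar_number(core_temp), core_temp >= 15, core_temp <= 45)
  structure(list(time = time, core_temp = core_temp), class = "plant_state")
}

# blanket coefficient for a speed
blanket_coefficient <- function(config, speed) {
  switch(speed,
         standby = 0,
         slow = config$k_blanket_slow,
         fast = config$k_blanket_fast)
}

#' Advance the plant by one Euler step
#'
#' Explicit-Euler update of the heat balance. With time constants of hours
#' the system is far from stiff at the 1 s step the 1 Hz loop uses.
#'
#' @param state A [plant_state].
#' @param setting The active [device_setting].
#' @param config A [plant_config].
#' @param dt Step in seconds (0 < dt <= 1 for integration accuracy).
#' @return The advanced [plant_state].
#' @export
plant_step <- function(state, setting, config, dt = 1) {
  stopifnot(inherits(state, "plant_state"), inherits(setting, "device_setting"),
            inherits(config, "plant_config"),
            is_scalar_number(dt), dt > 0, dt <= 1)
  p_met <- config$basal_metabolic_power + config$fever_profile(state$time)
  k_b <- blanket_coefficient(config, setting$speed)
  t_air <- delivered_air_temp(setting, config$ambient_temp)
  cap <- config$mass * config$specific_heat
  dT <- (p_met - config$k_ambient * (state$core_temp - config$ambient_temp) -
           k_b * (state$core_temp - t_air)) * dt / cap
  plant_state(time = state$time + dt, core_temp = state$core_temp + dT)
}

#' Steady-state temperature for a fixed setting
#'
#' Algebraic balance point `(P + k_a T_amb + k_b T_air) / (k_a + k_b)` of the
#' heat balance with constant metabolic power.
#'
#' @param setting A [device_setting].
#' @param config A [plant_config].
#' @param metabolic_power Constant power in W (default basal).
#' @return Equilibrium core temperature in degC.
#' @export
plant_equilibrium <- function(setting, config,
                              metabolic_power = config$basal_metabolic_power) {
  stopifnot(inherits(setting, "device_setting"), inherits(config, "plant_config"))
  k_b <- blanket_coefficient(config, setting$speed)
  t_air <- delivered_air_temp(setting, config$ambient_temp)
  (metabolic_power + config$k_ambient * config$ambient_temp + k_b * t_air) /
    (config$k_ambient + k_b)
}

#' Draw one measured temperature sample
#'
#' The measured value is the true core temperature plus Gaussian sensor noise
#' plus any scheduled artifact offset active at the current time. Artifact
#' samples are *not* flagged invalid — absorbing them is the controller's
#' averaging window's job.
#'
#' @param state A [plant_state].
#' @param config A [plant_config]; `noise_sd` and `artifact_schedule` apply.
#' @return A [temperature_sample] (always flagged valid).
#' @export
measure <- function(state, config) {
  stopifnot(inherits(state, "plant_state"), inherits(config, "plant_config"))
  temp <- state$core_temp +
    stats::rnorm(1L, 0, config$noise_sd) +
    artifact_offset_at(config$artifact_schedule, state$time)
  temperature_sample(time = state$time, temp = temp, valid = TRUE)
}

#' Simulate a full trial
#'
#' Rolls the plant forward at 1 Hz for `duration` seconds. With a
#' [controller_config] supplied the loop is closed: each second the measured
#' temperature is fed to the controller, and whenever an evaluation fires the
#' commanded setting is applied to an emulated warming unit through its
#' switch-press protocol. Without a controller the setting is held constant
#' (open loop; the default `(ambient, standby)` is the unmanaged scenario —
#' no blanket).
#'
#' @param config A [plant_config].
#' @param controller A [controller_config], or `NULL` for open loop.
#' @param duration Trial length in seconds (default 90 h, the planned study
#'   duration).
#' @param seed Seed for the measurement noise stream (default
#'   `config$seed`).
#' @param open_loop_setting Constant [device_setting] used when
#'   `controller` is `NULL`.
#' @param label Trial label stored in the series metadata.
#' @return A [trial_series] with an extra `core_temp_c` column carrying the
#'   true (noise-free) core temperature.
#' @examples
#' cfg <- plant_config(noise_sd = 0)
#' tr <- generate_trial(cfg, controller_config(), duration = 3600)
#' @export
generate_trial <- function(config, controller = NULL, duration = 324000,
                           seed = config$seed,
                           open_loop_setting = device_setting("ambient21", "standby"),
                           label = if (is.null(controller)) "open-loop" else "closed-loop") {
  stopifnot(inherits(config, "plant_config"),
            is.null(controller) || inherits(controller, "controller_config"),
            is_scalar_number(duration), duration >= 1)
  n <- as.integer(duration)
  if (!is.null(controller) && n < controller$eval_interval) {
    ttm_error("duration must cover at least one evaluation interval",
              "ttm_invalid_config")
  }
  times <- seq_len(n) - 1L

  # seeded measurement stream, RNG state restored afterwards
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
  art <- artifact_offset_at(config$artifact_schedule, times)
  p_met <- config$basal_metabolic_power + config$fever_profile(times)

  cap <- config$mass * config$specific_heat
  k_a <- config$k_ambient
  t_amb <- config$ambient_temp

  emu <- device_emulator(setting = if (is.null(controller)) open_loop_setting
                                   else state_to_setting(0))
  cur <- emulator_setting(emu)
  k_b <- blanket_coefficient(config, cur$speed)
  t_air <- delivered_air_temp(cur, t_amb)

  # controller scalars (inlined per-sample path; run_controller on the
  # recorded measurements reproduces the identical setting sequence)
  closed <- !is.null(controller)
  if (closed) {
    ct <- controller$eval_interval
    cs <- controller$scaling_factor
    tar <- controller$target_temp
    integral <- controller$mode == "integral"
    s <- 0
    last_eval <- times[1]
    wbuf_t <- numeric(2L * ct); wbuf_T <- numeric(2L * ct); wn <- 0L
  }

  core <- numeric(n)
  heat <- character(n)
  speed <- character(n)
  core[1] <- config$initial_temp

  for (i in seq_len(n)) {
    t <- times[i]
    if (closed) {
      wn <- wn + 1L
      if (wn > length(wbuf_t)) {  # gap-free 1 Hz never exceeds 2*ct
        wbuf_t <- c(wbuf_t, numeric(ct)); wbuf_T <- c(wbuf_T, numeric(ct))
      }
      wbuf_t[wn] <- t
      wbuf_T[wn] <- core[i] + noise[i] + art[i]
      if (t - last_eval >= ct) {
        keep <- wbuf_t[seq_len(wn)] > t - ct
        mbar <- mean(wbuf_T[seq_len(wn)][keep])
        e <- tar - mbar
        s <- clamp(if (integral) s + e * cs else e * cs, -1, 1)
        want <- state_to_setting(s)
        if (!setting_equal(want, cur)) {
          emulator_apply_setting(emu, want)
          cur <- emulator_setting(emu)
          k_b <- blanket_coefficient(config, cur$speed)
          t_air <- delivered_air_temp(cur, t_amb)
        }
        wn <- 0L
        last_eval <- t
      }
    }
    heat[i] <- cur$heat
    speed[i] <- cur$speed
    if (i < n) {
      core[i + 1] <- core[i] +
        (p_met[i] - k_a * (core[i] - t_amb) - k_b * (core[i] - t_air)) / cap
    }
  }

  trial_series(
    time_s = times,
    temp_c = core + noise + art,
    heat = heat,
    speed = speed,
    core_temp_c = core,
    label = label,
    target_temp = if (closed) controller$target_temp else NA_real_,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}
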
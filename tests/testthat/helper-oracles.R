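# Independent brute-force oracles the implementation is checked against.
# These deliberately re-derive everything from first principles: full-window
# recomputation of the mean, textbook clamp, literal setting table.

# per-sample controller oracle: grows a buffer, recomputes the mean from all
# stored samples at each evaluation, clears, repeats
oracle_controller <- function(time, temp, valid, config,
                              init_setting = state_to_setting(0)) {
  ct <- config$eval_interval
  cs <- config$scaling_factor
  tar <- config$target_temp
  s <- 0
  last_eval <- time[1]
  setting <- init_setting
  buf_t <- numeric(0); buf_x <- numeric(0); buf_v <- logical(0)
  out_t <- numeric(0); out_s <- numeric(0)
  out_heat <- character(0); out_speed <- character(0); out_data <- logical(0)
  for (i in seq_along(time)) {
    buf_t <- c(buf_t, time[i]); buf_x <- c(buf_x, temp[i]); buf_v <- c(buf_v, valid[i])
    if (time[i] - last_eval >= ct) {
      keep <- buf_v & buf_t > time[i] - ct
      had <- any(keep)
      if (had) {
        mbar <- mean(buf_x[keep])
        raw <- if (config$mode == "integral") s + (tar - mbar) * cs
               else (tar - mbar) * cs
        s <- if (raw >= 1) 1 else if (raw <= -1) -1 else raw
        setting <- oracle_setting_map(s)
      }
      out_t <- c(out_t, time[i]); out_s <- c(out_s, s)
      out_heat <- c(out_heat, setting$heat); out_speed <- c(out_speed, setting$speed)
      out_data <- c(out_data, had)
      buf_t <- numeric(0); buf_x <- numeric(0); buf_v <- logical(0)
      last_eval <- time[i]
    }
  }
  data.frame(time = out_t, s = out_s, heat = out_heat, speed = out_speed,
             has_data = out_data, stringsAsFactors = FALSE)
}

# literal transcription of the published setting table
oracle_setting_map <- function(s) {
  if (s == -1)            return(device_setting("ambient21", "fast"))
  if (-1 < s && s <= -0.5) return(device_setting("ambient21", "slow"))
  if (-0.5 < s && s <= 0)  return(device_setting("c32", "slow"))
  if (0 < s && s <= 0.5)   return(device_setting("c38", "slow"))
  if (0.5 < s && s < 1)    return(device_setting("c43", "slow"))
  if (s == 1)              return(device_setting("c43", "fast"))
  stop("s outside [-1, 1]")
}

# random 1 Hz-ish stream with gaps, drifting temperature and invalid samples
random_stream <- function(n, seed) {
  set.seed(seed)
  dt <- sample(c(1, 1, 1, 1, 2, 5), n, replace = TRUE)
  time <- cumsum(dt) - dt[1]
  temp <- 38 + cumsum(stats::rnorm(n, 0, 0.01)) + stats::rnorm(n, 0, 0.05)
  temp <- pmin(44.5, pmax(15.5, temp))
  valid <- stats::runif(n) > 0.03
  list(time = time, temp = temp, valid = valid)
}

random_config <- function(seed) {
  set.seed(seed + 10000L)
  controller_config(
    target_temp = stats::runif(1, 36, 40),
    eval_interval = sample(c(30L, 60L, 120L), 1),
    scaling_factor = stats::runif(1, 0.1, 2),
    mode = sample(c("integral", "proportional"), 1)
  )
}

# naive per-row metric oracles
oracle_within <- function(temps, target, tol) {
  outside <- 0L
  for (x in temps) if (abs(x - target) > tol) outside <- outside + 1L
  within_pct <- 100 * (length(temps) - outside) / length(temps)
  list(outside = outside, within_percent = floor(within_pct * 100 + 0.5) / 100)
}

oracle_changes <- function(heat, speed) {
  n <- 0L
  for (i in seq_along(heat)[-1]) {
    if (heat[i] != heat[i - 1] || speed[i] != speed[i - 1]) n <- n + 1L
  }
  n
}

# a trial series shaped to published per-trial aggregates: total duration,
# seconds outside +/-0.5 (but within +/-1.0), seconds outside +/-1.0, and
# number of setting transitions (SYNTHETIC stand-in; the recorded traces are
# not deposited)
synthetic_reference_series <- function(total, outside_half, outside_full,
                                       n_changes, target = 38, label) {
  temp <- rep(target, total)
  if (outside_full > 0) temp[seq_len(outside_full)] <- target + 1.2
  if (outside_half > outside_full) {
    temp[(outside_full + 1):outside_half] <- target + 0.7
  }
  seg <- floor(seq(0, total, length.out = n_changes + 2))  # n_changes+1 segments
  heat <- rep(rep(c("c38", "c32"), length.out = n_changes + 1), diff(seg))
  trial_series(time_s = 0:(total - 1), temp_c = temp, heat = heat,
               speed = rep("slow", total), label = label, target_temp = target)
}

# tiny deterministic series for IO and metric unit tests
make_series <- function(n = 10, temp = rep(38, n), heat = rep("c38", n),
                        speed = rep("slow", n), time = 0:(n - 1),
                        label = "fixture", target = 38) {
  trial_series(time_s = time, temp_c = temp, heat = heat, speed = speed,
               label = label, target_temp = target)
}
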
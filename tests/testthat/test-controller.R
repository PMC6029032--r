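test_that("window mean averages valid samples and signals on empty windows", {
  expect_equal(window_mean(list(temp = rep(38, 5), valid = rep(TRUE, 5))), 38)
  expect_equal(window_mean(list(temp = c(37.9, 38.1), valid = c(TRUE, TRUE))), 38)
  expect_equal(window_mean(list(temp = c(38.0, 30.0, 38.4),
                                valid = c(TRUE, FALSE, TRUE))), 38.2)
  expect_error(window_mean(list(temp = c(30, 31), valid = c(FALSE, FALSE))),
               class = "ttm_no_data")
  expect_error(window_mean(list(temp = numeric(0), valid = logical(0))),
               class = "ttm_no_data")
})

test_that("error is target minus mean: positive means heating needed", {
  expect_equal(compute_error(38.0, 38.0), 0)
  expect_equal(compute_error(38.5, 38.0), -0.5)
  expect_equal(compute_error(37.0, 38.0), 1.0)
})

test_that("state update accumulates scaled error and saturates at [-1, 1]", {
  expect_equal(update_state(0.0, 0.0, 0.7, "integral"), 0)
  expect_equal(update_state(0.9, 0.5, 0.7, "integral"), 1)
  expect_equal(update_state(0.0, -0.2, 0.7, "integral"), -0.14)
  expect_equal(update_state(-0.9, -0.5, 0.7, "integral"), -1)
  # proportional mode forgets the previous state and clamps
  expect_equal(update_state(0.6, 2.0, 0.7, "proportional"), 1)
  expect_equal(update_state(-0.3, 0.1, 0.7, "proportional"), 0.07)
  expect_error(update_state(1.2, 0, 0.7, "integral"),
               class = "ttm_contract_violation")
})

test_that("setting map hits the published anchor points and boundaries", {
  expect_true(setting_equal(state_to_setting(-1), device_setting("ambient21", "fast")))
  expect_true(setting_equal(state_to_setting(1), device_setting("c43", "fast")))
  expect_true(setting_equal(state_to_setting(0), device_setting("c32", "slow")))
  expect_true(setting_equal(state_to_setting(0.3), device_setting("c38", "slow")))
  # upper-inclusive interval boundaries
  expect_true(setting_equal(state_to_setting(-0.5), device_setting("ambient21", "slow")))
  expect_true(setting_equal(state_to_setting(0.5), device_setting("c38", "slow")))
  expect_true(setting_equal(state_to_setting(0.75), device_setting("c43", "slow")))
  expect_error(state_to_setting(1.01), class = "ttm_contract_violation")
  expect_error(state_to_setting(-2), class = "ttm_contract_violation")
})

test_that("setting map is monotone in heat and never returns standby", {
  grid <- seq(-1, 1, by = 0.005)
  settings <- lapply(grid, state_to_setting)
  ranks <- vapply(settings, function(x) match(x$heat, heat_levels), 0L)
  expect_true(all(diff(ranks) >= 0))
  expect_false(any(vapply(settings, function(x) x$speed, "") == "standby"))
})

test_that("stream held at target yields a constant neutral setting", {
  cfg <- controller_config()
  st <- controller_state()
  settings <- list()
  for (t in 0:360) {
    out <- controller_step(st, cfg, temperature_sample(t, 38.0))
    st <- out$state
    if (!is.null(out$setting)) settings[[length(settings) + 1]] <- out$setting
  }
  expect_length(settings, 3)  # evaluations at t = 120, 240, 360
  expect_true(all(vapply(settings, function(x)
    setting_equal(x, device_setting("c32", "slow")), TRUE)))
  expect_equal(st$s, 0)
})

test_that("a sustained cold step saturates the state and commands maximal heating", {
  # mean 36.5 against target 38: error 1.5, 1.5 * 0.7 = 1.05 clamps to 1
  cfg <- controller_config()
  st <- controller_state()
  first_setting <- NULL
  for (t in 0:120) {
    out <- controller_step(st, cfg, temperature_sample(t, 36.5))
    st <- out$state
    if (!is.null(out$setting) && is.null(first_setting)) first_setting <- out$setting
  }
  expect_equal(st$s, 1)
  expect_true(setting_equal(first_setting, device_setting("c43", "fast")))
})

test_that("an all-invalid window leaves state untouched and emits no setting", {
  cfg2 <- controller_config(eval_interval = 10L)
  st2 <- controller_state()
  st2$s <- 0.3
  st2$last_setting <- device_setting("c38", "slow")
  for (t in 0:9) {
    st2 <- controller_step(st2, cfg2, temperature_sample(t, 30, valid = FALSE))$state
  }
  out2 <- controller_step(st2, cfg2, temperature_sample(10, 30, valid = FALSE))
  expect_null(out2$setting)
  expect_equal(out2$state$s, 0.3)
  expect_true(setting_equal(out2$state$last_setting, device_setting("c38", "slow")))
  expect_length(out2$state$window$time, 0)  # window cleared, clock advanced
  expect_equal(out2$state$last_eval_time, 10)
})

test_that("out-of-order samples are rejected", {
  cfg <- controller_config()
  st <- controller_step(controller_state(), cfg, temperature_sample(5, 38))$state
  expect_error(controller_step(st, cfg, temperature_sample(4, 38)),
               class = "ttm_out_of_order")
  # equal timestamps (non-decreasing) are tolerated
  expect_silent(controller_step(st, cfg, temperature_sample(5, 38)))
})

test_that("negative feedback: held above target, integral state falls to -1", {
  cfg <- controller_config()
  res <- run_controller(time = 0:1800, temp = rep(39.0, 1801), config = cfg)
  s_seq <- res$evaluations$s
  pre_sat <- s_seq[s_seq > -1]
  expect_true(all(diff(res$evaluations$s) <= 0))
  expect_true(all(diff(pre_sat) < 0))       # strictly decreasing until saturation
  expect_equal(s_seq[length(s_seq)], -1)    # saturates at maximal cooling
})

test_that("state stays within [-1, 1] for arbitrary streams", {
  for (seed in 1:5) {
    stream <- random_stream(2000, seed)
    cfg <- random_config(seed)
    res <- run_controller(stream$time, stream$temp, stream$valid, cfg)
    expect_true(all(res$evaluations$s >= -1 & res$evaluations$s <= 1))
  }
})

test_that("per-sample stepping and the stream driver are equivalent", {
  for (seed in 1:8) {
    stream <- random_stream(2000, seed)
    cfg <- random_config(seed)
    res <- run_controller(stream$time, stream$temp, stream$valid, cfg)
    st <- controller_state(time0 = stream$time[1])
    step_t <- numeric(0); step_s <- numeric(0)
    step_heat <- character(0); step_speed <- character(0)
    for (i in seq_along(stream$time)) {
      before <- st$last_eval_time
      out <- controller_step(st, cfg, temperature_sample(
        stream$time[i], stream$temp[i], stream$valid[i]))
      st <- out$state
      if (st$last_eval_time != before) {  # an evaluation fired
        step_t <- c(step_t, st$last_eval_time)
        step_s <- c(step_s, st$s)
        step_heat <- c(step_heat, st$last_setting$heat)
        step_speed <- c(step_speed, st$last_setting$speed)
      }
    }
    expect_identical(step_t, res$evaluations$time)
    expect_identical(step_s, res$evaluations$s)
    expect_identical(step_heat, res$evaluations$heat)
    expect_identical(step_speed, res$evaluations$speed)
    expect_identical(st$s, res$state$s)
  }
})

test_that("identical streams and config give identical outputs", {
  stream <- random_stream(3000, 42)
  cfg <- controller_config()
  r1 <- run_controller(stream$time, stream$temp, stream$valid, cfg)
  r2 <- run_controller(stream$time, stream$temp, stream$valid, cfg)
  expect_identical(r1$evaluations, r2$evaluations)
})

test_that("flat key-value controller config files are parsed with defaults", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# study parameters", "target_temp_c = 37.5",
               "eval_interval_s: 60", "mode = proportional"), path)
  cfg <- read_controller_config(path)
  expect_equal(cfg$target_temp, 37.5)
  expect_equal(cfg$eval_interval, 60L)
  expect_equal(cfg$scaling_factor, 0.7)  # default retained
  expect_equal(cfg$mode, "proportional")
  expect_error(controller_config(target_temp = 50), class = "ttm_invalid_config")
  expect_error(controller_config(eval_interval = 0), class = "ttm_invalid_config")
  expect_error(controller_config(scaling_factor = -1), class = "ttm_invalid_config")
})
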
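all_settings <- function() {
  out <- list()
  for (h in heat_levels) for (sp in speed_levels) {
    out[[length(out) + 1]] <- device_setting(h, sp)
  }
  out
}

test_that("setting constructor normalizes dialects and rejects nonsense", {
  expect_true(setting_equal(device_setting("38", "slow"),
                            device_setting("c38", "slow")))
  expect_true(setting_equal(device_setting(21, "fast"),
                            device_setting("ambient21", "fast")))
  expect_true(setting_equal(device_setting("ambient", "standby"),
                            device_setting("ambient21", "standby")))
  expect_error(device_setting("c99", "slow"), class = "ttm_invalid_setting")
  expect_error(device_setting("c38", "warp"), class = "ttm_invalid_setting")
})

test_that("status frames follow the canonical ten-bit payload", {
  f <- encode_status(device_status(fault = FALSE, temp_in_range = TRUE,
                                   speed = "slow", heat = "c38"))
  expect_equal(f$payload, "0101000100")
  expect_equal(encode_status(device_status())$payload, "0000000000")
  expect_equal(
    encode_status(device_status(fault = TRUE, speed = "fast", heat = "ambient21",
                                reserved = TRUE))$payload,
    "1000110001")
})

test_that("status codec roundtrips over every reachable indicator state", {
  n_checked <- 0L
  for (fault in c(FALSE, TRUE)) for (rng in c(FALSE, TRUE)) {
    for (sp in c("off", speed_levels)) for (h in c("off", heat_levels)) {
      for (res in c(FALSE, TRUE)) {
        st <- device_status(fault, rng, sp, h, res)
        expect_equal(decode_status(encode_status(st)), st)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 160L)
})

test_that("malformed status frames are rejected with protocol errors", {
  expect_error(decode_status(protocol_frame("010100010")),   # 9 chars
               class = "ttm_protocol_error")
  expect_error(decode_status(protocol_frame("01010001000")), # 11 chars
               class = "ttm_protocol_error")
  expect_error(decode_status(protocol_frame("0101002100")),  # bad alphabet
               class = "ttm_protocol_error")
  expect_error(decode_status(protocol_frame("0011000000")),  # two speed lamps
               class = "ttm_protocol_error")
  expect_error(decode_status(protocol_frame("0000011000")),  # two heat lamps
               class = "ttm_protocol_error")
})

test_that("byte-level framing is STX payload ETX with a clean payload", {
  f <- protocol_frame("S:3")
  b <- frame_bytes(f)
  expect_identical(b[1], as.raw(2))
  expect_identical(b[length(b)], as.raw(3))
  expect_equal(parse_frame(b), f)
  expect_error(parse_frame(c(charToRaw("S:3"), as.raw(3))),
               class = "ttm_protocol_error")  # missing STX
  expect_error(parse_frame(c(as.raw(2), charToRaw("S:3"))),
               class = "ttm_protocol_error")  # missing ETX
  expect_error(protocol_frame(rawToChar(as.raw(c(65, 2, 66)))),
               class = "ttm_protocol_error")  # STX inside payload
})

test_that("switch commands encode as S:X and roundtrip for switches 1-8", {
  expect_equal(encode_command(3)$payload, "S:3")
  for (k in 1:8) expect_equal(decode_command(encode_command(k)), k)
  expect_error(encode_command(0), class = "ttm_invalid_switch")
  expect_error(encode_command(9), class = "ttm_invalid_switch")
  expect_error(decode_command(protocol_frame("S:9")), class = "ttm_protocol_error")
  expect_error(decode_command(protocol_frame("X:1")), class = "ttm_protocol_error")
})

test_that("switch presses select speed (1-3) and heat (4-7), 8 is a no-op", {
  expect_true(setting_equal(press_switch(device_setting("ambient21", "slow"), 7),
                            device_setting("c43", "slow")))
  expect_true(setting_equal(press_switch(device_setting("c38", "fast"), 2),
                            device_setting("c38", "slow")))
  # idempotent re-press of the active selection
  expect_true(setting_equal(press_switch(device_setting("c38", "slow"), 6),
                            device_setting("c38", "slow")))
  expect_true(setting_equal(press_switch(device_setting("c38", "slow"), 8),
                            device_setting("c38", "slow")))
  # every press on every setting yields a valid setting
  for (s in all_settings()) for (k in 1:8) {
    r <- press_switch(s, k)
    expect_true(r$heat %in% heat_levels && r$speed %in% speed_levels)
  }
})

test_that("press planning is minimal and correct over all 144 transitions", {
  settings <- all_settings()
  n_checked <- 0L
  for (cur in settings) for (tar in settings) {
    plan <- presses_for_transition(cur, tar)
    reached <- Reduce(press_switch, plan, cur)
    expect_true(setting_equal(reached, tar))
    needed <- (cur$heat != tar$heat) + (cur$speed != tar$speed)
    expect_length(plan, needed)   # minimal: one press per differing component
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 144L)
})

test_that("airflow and delivered air temperature match the device ratings", {
  expect_equal(airflow("fast"), 23)
  expect_equal(airflow("slow"), 20)
  expect_equal(airflow("standby"), 0)
  expect_equal(delivered_air_temp(device_setting("c38", "slow")), 38)
  expect_equal(delivered_air_temp(device_setting("ambient21", "fast"),
                                  ambient = 21), 21)
  expect_equal(delivered_air_temp(device_setting("c43", "slow"), bias = 1), 44)
  expect_error(delivered_air_temp(device_setting("c43", "slow"), bias = 2),
               class = "ttm_invalid_setting")
})

test_that("the emulator tracks presses received over the protocol", {
  emu <- device_emulator(device_setting("c32", "slow"))
  emulator_receive(emu, encode_command(7))
  emulator_receive(emu, encode_command(3))
  expect_true(setting_equal(emulator_setting(emu), device_setting("c43", "fast")))
  # status frame reflects the new state and decodes back
  st <- decode_status(parse_frame(frame_bytes(emulator_status_frame(emu))))
  expect_true(setting_equal(status_setting(st), device_setting("c43", "fast")))
  expect_false(st$fault)
  # planned transition drives the emulator to any target
  emulator_apply_setting(emu, device_setting("ambient21", "standby"))
  expect_true(setting_equal(emulator_setting(emu),
                            device_setting("ambient21", "standby")))
  expect_error(status_setting(device_status()), class = "ttm_protocol_error")
})
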
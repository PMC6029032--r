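#' Heat and speed levels of the forced-air warming unit
#'
#' The emulated warming unit offers four discrete heat levels — unheated
#' ambient air (about 21 degC in a typical room) and three heated set points
#' at 32, 38 and 43 degC — and three blower speeds. The `standby` speed
#' deflates the blanket and is never commanded by the controller.
#'
#' @format Character vectors of the canonical level names, ordered from
#'   coldest to hottest (`heat_levels`) and slowest to fastest
#'   (`speed_levels`).
#' @export
heat_levels <- c("ambient21", "c32", "c38", "c43")

#' @rdname heat_levels
#' @export
speed_levels <- c("standby", "slow", "fast")

# nominal delivered-air temperature per heat level; ambient is resolved at
# call time from the room temperature
.heat_nominal <- c(ambient21 = NA_real_, c32 = 32, c38 = 38, c43 = 43)

#' Actuator setting of the warming unit
#'
#' A device setting is the command tuple `(heat, speed)` applied to the
#' warming unit. Exactly one heat level and one speed are active at a time.
#'
#' @param heat One of [heat_levels]. Numeric shorthand (`21`, `32`, `38`,
#'   `43`) and bare strings (`"38"`, `"ambient"`) are accepted and
#'   normalized.
#' @param speed One of [speed_levels].
#' @return An object of class `device_setting`: a list with elements `heat`
#'   and `speed`.
#' @examples
#' device_setting("c38", "slow")
#' device_setting(43, "fast")
#' @export
device_setting <- function(heat, speed) {
  heat <- normalize_heat(heat)
  speed <- normalize_speed(speed)
  structure(list(heat = heat, speed = speed), class = "device_setting")
}

#' @export
format.device_setting <- function(x, ...) {
  lab <- c(ambient21 = "ambient 21 °C", c32 = "32 °C",
           c38 = "38 °C", c43 = "43 °C")
  sprintf("(%s, %s)", lab[[x$heat]], x$speed)
}

#' @export
print.device_setting <- function(x, ...) {
  cat("<device_setting>", format(x), "\n")
  invisible(x)
}

#' Compare two device settings
#'
#' @param a,b `device_setting` objects.
#' @return `TRUE` when heat and speed both match.
#' @export
setting_equal <- function(a, b) {
  identical(a$heat, b$heat) && identical(a$speed, b$speed)
}

# map assorted spellings onto the canonical level names
normalize_heat <- function(heat) {
  if (length(heat) != 1L) ttm_error("heat must be a single value", "ttm_invalid_setting")
  h <- tolower(as.character(heat))
  map <- c("ambient21" = "ambient21", "ambient" = "ambient21", "amb" = "ambient21",
           "21" = "ambient21",
           "c32" = "c32", "32" = "c32",
           "c38" = "c38", "38" = "c38",
           "c43" = "c43", "43" = "c43")
  out <- unname(map[h])
  if (is.na(out)) {
    ttm_error(sprintf("unknown heat level '%s' (expected one of %s)",
                      heat, paste(heat_levels, collapse = ", ")),
              "ttm_invalid_setting")
  }
  out
}

normalize_speed <- function(speed) {
  if (length(speed) != 1L) ttm_error("speed must be a single value", "ttm_invalid_setting")
  s <- tolower(as.character(speed))
  if (!s %in% speed_levels) {
    ttm_error(sprintf("unknown speed '%s' (expected one of %s)",
                      speed, paste(speed_levels, collapse = ", ")),
              "ttm_invalid_setting")
  }
  s
}

# rank of a heat level under the order ambient21 < 32 < 38 < 43
heat_rank <- function(heat) match(heat, heat_levels)

#' Indicator (LED) status of the warming unit
#'
#' The unit exposes its state through ten front-panel indicators, read out as
#' one bit each: a fault lamp, a temperature-in-range lamp, one lamp per
#' speed, one lamp per heat level, and a tenth reserved (unassigned)
#' indicator. Between mode changes — or with the unit powered off — a speed
#' or heat group may show no lit lamp, so `"off"` is allowed here even though
#' an actuator command ([device_setting]) always names one level per group.
#'
#' @param fault Logical; fault lamp lit.
#' @param temp_in_range Logical; delivered-air-temperature-in-range lamp lit.
#' @param speed One of `"off"` or [speed_levels].
#' @param heat One of `"off"` or [heat_levels].
#' @param reserved Logical; the unassigned tenth indicator.
#' @return An object of class `device_status`.
#' @seealso [encode_status()], [decode_status()]
#' @export
device_status <- function(fault = FALSE, temp_in_range = FALSE,
                          speed = "off", heat = "off", reserved = FALSE) {
  speed <- if (identical(speed, "off")) "off" else normalize_speed(speed)
  heat <- if (identical(heat, "off")) "off" else normalize_heat(heat)
  stopifnot(is.logical(fault), length(fault) == 1L,
            is.logical(temp_in_range), length(temp_in_range) == 1L,
            is.logical(reserved), length(reserved) == 1L)
  structure(list(fault = fault, temp_in_range = temp_in_range,
                 speed = speed, heat = heat, reserved = reserved),
            class = "device_status")
}

#' @export
print.device_status <- function(x, ...) {
  cat("<device_status> fault:", x$fault,
      " in-range:", x$temp_in_range,
      " speed:", x$speed, " heat:", x$heat,
      " reserved:", x$reserved, "\n")
  invisible(x)
}

#' Extract the actuator setting from a status
#'
#' @param status A [device_status].
#' @return A [device_setting].
#' @export
status_setting <- function(status) {
  if (identical(status$speed, "off") || identical(status$heat, "off")) {
    ttm_error("status has no active speed/heat; no setting defined",
              "ttm_protocol_error")
  }
  device_setting(status$heat, status$speed)
}

# canonical indicator (bit) order of the status payload
status_bit_names <- c("fault", "temp_in_range", "standby", "slow", "fast",
                      "ambient21", "c32", "c38", "c43", "reserved")

#' Serial protocol frames
#'
#' Every message on the serial link is plain ASCII framed by a start byte
#' `0x02` (STX) and an end byte `0x03` (ETX). The payload itself never
#' contains either framing byte.
#'
#' @param payload Single character string (ASCII, no STX/ETX).
#' @return `protocol_frame()` returns an object of class `protocol_frame`;
#'   `frame_bytes()` returns the raw on-wire byte vector; `parse_frame()`
#'   validates a raw vector and returns the `protocol_frame` it carries.
#' @examples
#' f <- protocol_frame("S:3")
#' frame_bytes(f)
#' parse_frame(frame_bytes(f))
#' @export
protocol_frame <- function(payload) {
  stopifnot(is.character(payload), length(payload) == 1L)
  raw <- charToRaw(payload)
  if (any(raw %in% as.raw(c(2L, 3L)))) {
    ttm_error("payload must not contain STX/ETX bytes", "ttm_protocol_error")
  }
  structure(list(payload = payload), class = "protocol_frame")
}

#' @rdname protocol_frame
#' @param frame A `protocol_frame`.
#' @export
frame_bytes <- function(frame) {
  stopifnot(inherits(frame, "protocol_frame"))
  c(as.raw(2L), charToRaw(frame$payload), as.raw(3L))
}

#' @rdname protocol_frame
#' @param bytes Raw vector: one full frame, STX first and ETX last.
#' @export
parse_frame <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) < 2L) {
    ttm_error("frame must be a raw vector of at least 2 bytes", "ttm_protocol_error")
  }
  if (bytes[1L] != as.raw(2L) || bytes[length(bytes)] != as.raw(3L)) {
    ttm_error("malformed framing: expected STX (0x02) ... ETX (0x03)",
              "ttm_protocol_error")
  }
  body <- bytes[-c(1L, length(bytes))]
  if (any(body %in% as.raw(c(2L, 3L)))) {
    ttm_error("payload contains framing bytes", "ttm_protocol_error")
  }
  protocol_frame(rawToChar(body))
}

#' @export
print.protocol_frame <- function(x, ...) {
  cat(sprintf("<protocol_frame> STX|%s|ETX\n", x$payload))
  invisible(x)
}

#' Encode a device status as a protocol frame
#'
#' The ten indicator states are serialized as a 10-character string of `0`s
#' and `1`s in the canonical order fault, temp-in-range, standby, slow, fast,
#' ambient, 32, 38, 43, reserved. The emulated unit emits one such frame per
#' second.
#'
#' @param status A [device_status].
#' @param bit_order Character vector naming the indicator order; the default
#'   is the canonical order above. The true pin order of the original add-on
#'   board is unpublished, hence configurable.
#' @return A [protocol_frame] with a 10-character binary payload.
#' @examples
#' encode_status(device_status(temp_in_range = TRUE, speed = "slow", heat = "c38"))
#' @export
encode_status <- function(status, bit_order = status_bit_names) {
  stopifnot(inherits(status, "device_status"),
            setequal(bit_order, status_bit_names))
  bits <- c(
    fault = status$fault,
    temp_in_range = status$temp_in_range,
    standby = identical(status$speed, "standby"),
    slow = identical(status$speed, "slow"),
    fast = identical(status$speed, "fast"),
    ambient21 = identical(status$heat, "ambient21"),
    c32 = identical(status$heat, "c32"),
    c38 = identical(status$heat, "c38"),
    c43 = identical(status$heat, "c43"),
    reserved = status$reserved
  )
  protocol_frame(paste(as.integer(bits[bit_order]), collapse = ""))
}

#' Decode a status frame
#'
#' Inverse of [encode_status()]. Rejects payloads of the wrong length or
#' alphabet and physically impossible indicator combinations (more than one
#' speed or heat lamp lit).
#'
#' @inheritParams encode_status
#' @param frame A [protocol_frame] carrying a 10-character binary payload.
#' @return A [device_status].
#' @export
decode_status <- function(frame, bit_order = status_bit_names) {
  stopifnot(inherits(frame, "protocol_frame"),
            setequal(bit_order, status_bit_names))
  p <- frame$payload
  if (nchar(p) != 10L) {
    ttm_error(sprintf("status payload must have 10 characters, got %d", nchar(p)),
              "ttm_protocol_error")
  }
  ch <- strsplit(p, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("0", "1"))) {
    ttm_error("status payload must consist of '0'/'1' only", "ttm_protocol_error")
  }
  bits <- as.logical(as.integer(ch))
  names(bits) <- bit_order
  speed_on <- speed_levels[bits[speed_levels]]
  heat_on <- heat_levels[bits[heat_levels]]
  if (length(speed_on) > 1L) {
    ttm_error("conflicting status: more than one speed indicator lit",
              "ttm_protocol_error")
  }
  if (length(heat_on) > 1L) {
    ttm_error("conflicting status: more than one heat indicator lit",
              "ttm_protocol_error")
  }
  device_status(
    fault = unname(bits["fault"]),
    temp_in_range = unname(bits["temp_in_range"]),
    speed = if (length(speed_on)) speed_on else "off",
    heat = if (length(heat_on)) heat_on else "off",
    reserved = unname(bits["reserved"])
  )
}

#' Encode and decode switch-press commands
#'
#' A remote press of front-panel switch `X` (1-8) is requested with the ASCII
#' command `S:X`.
#'
#' @param switch_number Integer in 1..8.
#' @return `encode_command()` returns the [protocol_frame]; `decode_command()`
#'   returns the switch number carried by a command frame.
#' @examples
#' encode_command(3)
#' decode_command(protocol_frame("S:7"))
#' @export
encode_command <- function(switch_number) {
  switch_number <- check_switch(switch_number)
  protocol_frame(sprintf("S:%d", switch_number))
}

#' @rdname encode_command
#' @param frame A [protocol_frame].
#' @export
decode_command <- function(frame) {
  stopifnot(inherits(frame, "protocol_frame"))
  p <- frame$payload
  if (!grepl("^S:[1-8]$", p)) {
    ttm_error(sprintf("malformed command payload '%s' (expected S:1 .. S:8)", p),
              "ttm_protocol_error")
  }
  as.integer(substring(p, 3L, 3L))
}

check_switch <- function(switch_number) {
  if (!is_scalar_number(switch_number) || switch_number != round(switch_number) ||
      switch_number < 1 || switch_number > 8) {
    ttm_error(sprintf("switch number must be an integer in 1..8, got %s",
                      paste(switch_number, collapse = ",")),
              "ttm_invalid_switch")
  }
  as.integer(switch_number)
}

# canonical switch assignment: 1-3 select the speed, 4-7 the heat level,
# 8 is unassigned (the true wiring is unpublished)
.switch_speed <- c(`1` = "standby", `2` = "slow", `3` = "fast")
.switch_heat <- c(`4` = "ambient21", `5` = "c32", `6` = "c38", `7` = "c43")

#' Apply a front-panel switch press to a setting
#'
#' Switches 1-3 select the blower speed (standby, slow, fast), switches 4-7
#' the heat level (ambient, 32, 38, 43 degC) and switch 8 is unassigned
#' (no-op). Pressing the already-active selection leaves the setting
#' unchanged. The physical 150 ms press is modeled as an instantaneous
#' discrete event.
#'
#' @param setting Current [device_setting].
#' @param switch_number Integer in 1..8.
#' @return The resulting [device_setting].
#' @examples
#' press_switch(device_setting("ambient21", "slow"), 7)  # heat to 43 degC
#' @export
press_switch <- function(setting, switch_number) {
  stopifnot(inherits(setting, "device_setting"))
  k <- check_switch(switch_number)
  if (k <= 3L) {
    device_setting(setting$heat, .switch_speed[[as.character(k)]])
  } else if (k <= 7L) {
    device_setting(.switch_heat[[as.character(k)]], setting$speed)
  } else {
    setting
  }
}

#' Plan the switch presses for a setting transition
#'
#' Returns the minimal press sequence (length 0-2, heat before speed) that
#' maps `current` to `target` under [press_switch()].
#'
#' @param current,target [device_setting] objects.
#' @return Integer vector of switch numbers (possibly empty).
#' @examples
#' presses_for_transition(device_setting("c32", "slow"), device_setting("c43", "fast"))
#' @export
presses_for_transition <- function(current, target) {
  stopifnot(inherits(current, "device_setting"), inherits(target, "device_setting"))
  presses <- integer(0)
  if (!identical(current$heat, target$heat)) {
    presses <- c(presses, as.integer(names(.switch_heat)[match(target$heat, .switch_heat)]))
  }
  if (!identical(current$speed, target$speed)) {
    presses <- c(presses, as.integer(names(.switch_speed)[match(target$speed, .switch_speed)]))
  }
  presses
}

#' Blower airflow for a speed setting
#'
#' @param speed One of [speed_levels].
#' @return Airflow in L/s: 23 for `fast`, 20 for `slow`, 0 in `standby`.
#' @export
airflow <- function(speed) {
  speed <- normalize_speed(speed)
  c(standby = 0, slow = 20, fast = 23)[[speed]]
}

#' Delivered air temperature of a setting
#'
#' The heated levels deliver their nominal set point (32/38/43 degC, held by
#' the unit within +/-1.5 degC); the ambient level delivers room air.
#'
#' @param setting A [device_setting].
#' @param ambient Room temperature in degC (default 21).
#' @param bias Optional emulated set-point bias in degC, bounded to
#'   \[-1.5, 1.5\]; applied to the heated levels only.
#' @return Delivered air temperature in degC.
#' @export
delivered_air_temp <- function(setting, ambient = 21, bias = 0) {
  stopifnot(inherits(setting, "device_setting"), is_scalar_number(ambient),
            is_scalar_number(bias))
  if (abs(bias) > 1.5) {
    ttm_error("set-point bias must lie within +/-1.5 degC", "ttm_invalid_setting")
  }
  if (setting$heat == "ambient21") {
    ambient
  } else {
    .heat_nominal[[setting$heat]] + bias
  }
}

# documentation constants of the original serial link; no bit-level timing is
# emulated
serial_link_constants <- list(baud = 9600L, press_ms = 150L, quartz_mhz = 15.7456)
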
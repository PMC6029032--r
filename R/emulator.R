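#' Software emulator of the warming unit
#'
#' A stateful stand-in for the physical warming unit plus its serial add-on
#' board. The emulator holds the current actuator setting, accepts switch
#' commands either directly ([emulator_press()]) or as protocol frames
#' ([emulator_receive()]), and reports its indicator state as a status frame
#' ([emulator_status_frame()]); the original board pushes one such frame per
#' second, so drive [emulator_status_frame()] once per simulated second.
#'
#' @param setting Initial [device_setting] (default 32 degC, slow — the
#'   neutral mid-range setting).
#' @param fault Initial fault-lamp state.
#' @param temp_in_range Initial in-range-lamp state.
#' @return An object of class `device_emulator` (an environment).
#' @examples
#' emu <- device_emulator()
#' emulator_receive(emu, encode_command(7))
#' emulator_setting(emu)
#' @export
device_emulator <- function(setting = device_setting("c32", "slow"),
                            fault = FALSE, temp_in_range = TRUE) {
  stopifnot(inherits(setting, "device_setting"))
  emu <- new.env(parent = emptyenv())
  emu$setting <- setting
  emu$fault <- isTRUE(fault)
  emu$temp_in_range <- isTRUE(temp_in_range)
  emu$press_log <- integer(0)
  class(emu) <- "device_emulator"
  emu
}

#' @rdname device_emulator
#' @param emu A `device_emulator`.
#' @export
emulator_setting <- function(emu) {
  stopifnot(inherits(emu, "device_emulator"))
  emu$setting
}

#' @rdname device_emulator
#' @param switch_number Integer in 1..8.
#' @export
emulator_press <- function(emu, switch_number) {
  stopifnot(inherits(emu, "device_emulator"))
  k <- check_switch(switch_number)
  emu$setting <- press_switch(emu$setting, k)
  emu$press_log <- c(emu$press_log, k)
  invisible(emu$setting)
}

#' @rdname device_emulator
#' @param frame A command [protocol_frame] (payload `S:X`).
#' @export
emulator_receive <- function(emu, frame) {
  emulator_press(emu, decode_command(frame))
}

#' @rdname device_emulator
#' @export
emulator_status <- function(emu) {
  stopifnot(inherits(emu, "device_emulator"))
  device_status(fault = emu$fault, temp_in_range = emu$temp_in_range,
                speed = emu$setting$speed, heat = emu$setting$heat)
}

#' @rdname device_emulator
#' @export
emulator_status_frame <- function(emu) {
  encode_status(emulator_status(emu))
}

#' Drive an emulator to a target setting over the protocol
#'
#' Plans the minimal press sequence with [presses_for_transition()], encodes
#' each press as a command frame, and feeds the frames to the emulator —
#' the full round trip the closed loop uses.
#'
#' @param emu A [device_emulator].
#' @param target Target [device_setting].
#' @return The emulator's setting after the transition (equals `target`).
#' @export
emulator_apply_setting <- function(emu, target) {
  stopifnot(inherits(emu, "device_emulator"), inherits(target, "device_setting"))
  for (k in presses_for_transition(emulator_setting(emu), target)) {
    emulator_receive(emu, encode_command(k))
  }
  emulator_setting(emu)
}

#' @export
print.device_emulator <- function(x, ...) {
  cat("<device_emulator>", format(x$setting),
      sprintf(" presses: %d\n", length(x$press_log)))
  invisible(x)
}
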
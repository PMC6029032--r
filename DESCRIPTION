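Package: ttmloop
Title: Closed-Loop Targeted Temperature Management with Forced-Air Warming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, emulation and evaluation toolkit for automated
    targeted temperature management (TTM) with a forced-air warming unit.
    Implements an annealing feedback controller with a saturating control
    state and a quantized setting map, a software emulator of a forced-air
    warming device including its serial status/command protocol (STX/ETX
    framed ASCII frames, switch-press commands), a lumped-parameter thermal
    model of an anesthetized subject with fever drift and measurement
    artifacts for closed-loop simulation, and replay/metrics tools for 1 Hz
    trial recordings: time-in-range fractions, setting-change rates and
    sliding-median filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
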
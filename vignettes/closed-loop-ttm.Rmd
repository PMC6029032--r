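---
title: "Closed-loop targeted temperature management: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop targeted temperature management: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttmloop)
```

## The problem

Anesthetized patients cannot thermoregulate: depending on drapes, room
temperature, medication and metabolic state, core temperature drifts — often
downwards in the operating room, often upwards (medication-associated fever)
in prolonged narcosis. Targeted temperature management (TTM) with a
forced-air warming blanket is the common non-invasive countermeasure, but the
warming unit only offers a handful of discrete settings and is normally
re-adjusted by hand every so often. `ttmloop` implements a complete automated
loop around such a unit and the tooling to evaluate it: a feedback controller,
a software emulator of the device and its serial protocol, a thermal model of
the subject to close the loop against, and metrics for 1 Hz trial recordings.

## The control algorithm

Every second the loop receives one blood-temperature reading $T_t$ from the
patient monitor. Readings are collected into an evaluation window of length
$c_t$ seconds (default 120 s) and averaged,

$$\bar T_t = \mathrm{mean}\{\,T_i : t - c_t < i \le t,\ i \text{ valid}\,\},$$

which is the controller's only defense against short measurement artifacts
(catheter flushes, the cold-fluid injections used to recalibrate cardiac
output). At each evaluation the temperature error is

$$e_t = T_{tar} - \bar T_t,$$

positive when the subject is too cold. We use the negative-feedback sign
convention throughout: the saturating control state defined next maps $+1$ to
maximal heating, so the error must be positive when heating is needed.
The state accumulates the scaled error and is clamped,

$$s_t = \mathrm{clamp}\bigl(s_{t-1} + e_t\, c_s,\ [-1, 1]\bigr), \qquad s_0 = 0,$$

with scaling factor $c_s$ (default 0.7 per degC, the value tuned empirically
for a porcine ICU setting). This integral ("annealing") form is the default
mode: the controller walks towards the extreme settings in several steps and,
because the state saturates rather than winding up, it can always return from
an extreme within a few evaluations once the error reverses. A memory-free
proportional mode ($s_t = \mathrm{clamp}(e_t c_s)$) is selectable for
comparison.

Finally the continuous state is quantized onto the six usable device
settings:

| state $s$            | setting            |
|----------------------|--------------------|
| $s = -1$             | (ambient 21 °C, fast) — maximal cooling |
| $-1 < s \le -0.5$    | (ambient 21 °C, slow) |
| $-0.5 < s \le 0$     | (32 °C, slow)      |
| $0 < s \le 0.5$      | (38 °C, slow)      |
| $0.5 < s < 1$        | (43 °C, slow)      |
| $s = 1$              | (43 °C, fast) — maximal heating |

Intervals are upper-inclusive; the `standby` speed is never commanded because
it deflates the blanket. Speed changes only occur at the saturated endpoints —
the airflow difference (23 vs 20 L/s) matters far less than the air
temperature, so the algorithm manages mainly by heat level.

Three choices here were genuinely open and are worth recording:

* **Error sign.** With the state convention "$+1$ = maximal heating", the
  error must be target-minus-measurement; the opposite sign would heat an
  already-hot subject. `compute_error()` implements $T_{tar} - \bar T_t$.
* **Integral vs proportional.** The accumulating form is the default: it is
  the variant for which the $s_0 = 0$ initialization is meaningful and which
  adapts to whatever steady heating/cooling demand the individual subject
  has — a proportional map from a 1–2 °C error range could never reach the
  extreme settings under realistic errors with $c_s = 0.7$.
* **Partition completeness.** The six intervals above tile $[-1,1]$ with no
  gaps or overlaps; the test suite sweeps the interval to verify exactly one
  setting per state and monotone heat ordering.

### Evaluation clock and window semantics

Evaluations fire on wall-clock seconds: the first sample whose timestamp is
at least $c_t$ seconds after the previous evaluation triggers one. The window
is cleared after each evaluation and refilled ("collect, average, adapt,
repeat"); within an evaluation only valid samples from the trailing $c_t$
seconds enter the mean, so after a data gap stale samples are excluded. A
window with no valid sample leaves the state untouched and keeps the previous
setting — the device simply stays where it was. A partially filled first
window is evaluated as-is.

`controller_step()` is the faithful one-sample-at-a-time operation;
`run_controller()` iterates over evaluation boundaries so that multi-day 1 Hz
recordings replay in milliseconds. The two are checked against each other,
and against an independent brute-force re-computation, on randomized streams
with gaps and invalid samples.

## The device and its protocol

The emulated warming unit has four heat levels (ambient ≈21 °C, 32, 38,
43 °C, the heated ones held within ±1.5 °C by the unit) and three blower
speeds (standby/slow/fast; 0/20/23 L/s). The original hardware interface read
ten indicator LEDs and actuated eight front-panel switches; neither the LED
pin order nor the switch wiring is published, so the package fixes a
canonical convention and documents it:

* status bits, in order: fault, temperature-in-range, standby, slow, fast,
  ambient, 32 °C, 38 °C, 43 °C, reserved (the tenth indicator is unassigned);
* switches: 1–3 select the speed, 4–7 the heat level, 8 is unassigned.

Status frames are the ten bits as an ASCII `0`/`1` string, commands are
`S:X` with `X` the switch number, and every message is framed by STX (0x02)
and ETX (0x03). The codec is byte-exact and round-trip tested over every
reachable indicator state; `presses_for_transition()` plans the minimal
press sequence (at most one heat press then one speed press) and is verified
by exhaustive enumeration of all 144 setting transitions. The 9600 baud rate
and the 150 ms press duration of the original board are kept as
documentation constants only — presses are modeled as instantaneous discrete
events, and no checksumming exists in the protocol by design.

## The thermal plant

The package needs a subject to close the loop against; the study system
itself provides none, so `plant_config()` defines the minimal lumped model
that reproduces the relevant phenomenology — fever drift when uncontrolled,
and ramp-and-correct alternation under quantized control:

$$C\,\frac{dT}{dt} = P_{met}(t) - k_{amb}\,(T - T_{amb}) - k_{bl}(\text{speed})\,(T - T_{air}(\text{setting}))$$

with heat capacity $C = m c$ and metabolic power
$P_{met}(t) = P_{basal} + \text{fever}(t)$. Defaults, chosen once for a
~42 kg anesthetized pig fully covered by the blanket:

| parameter | default | rationale |
|---|---|---|
| mass $m$ | 42 kg | study animals averaged 40–45 kg |
| specific heat $c$ | 3500 J/(kg K) | typical whole-body tissue average |
| $k_{amb}$ | 5 W/K | passive loss of a draped subject at 21 °C room air |
| $k_{bl}$ slow/fast | 18 / 25 W/K | bounded by the airflow heat-capacity rate $\dot m c_p$ ≈ 24 / 28 W/K at 20 / 23 L/s; effectiveness < 1 |
| $P_{basal}$ | 90 W | ≈2.1 W/kg, upper-normal basal rate under TIVA |
| fever | ramp to +15 W from 4 h over 8 h | slow medication-associated fever of prolonged narcosis |
| $T_{amb}$ | 21 °C | room temperature |
| initial $T$ | 37.5 °C | mild heat loss accrued during instrumentation |
| noise sd | 0.05 °C | arterial catheter thermistor noise |
| artifacts | −2 °C for 30 s every 4 h (opt-in schedule) | cold-injectate calibration dips and flushes |

These values put the uncontrolled equilibrium at 39 °C basal and 42 °C at
full fever, so an unmanaged subject drifts febrile within about a day, while
maximal cooling (ambient air, fast blower; balance point ≈24 °C) retains
ample authority. Deliberately, *no* single setting balances exactly at
38.0 °C (the nearest balance points are ≈33.5 and ≈38.2 °C), so the closed
loop must alternate between adjacent settings — the small sawtooth ramps
characteristic of a quantized actuator.

Integration is explicit Euler at $dt \le 1$ s. The time constants are
$C/k \approx 1.7$–8 h, five orders of magnitude above the step, so stiffness
is not a concern; in the homogeneous case the trajectory is checked against
the exact exponential solution and agrees to better than $10^{-4}$ °C over
two hours. Measurement noise and artifact offsets apply to the *measured*
channel only; artifacts are not pre-flagged as invalid, because absorbing
them is the averaging window's job. A generated trial stores both the
measured channel (`temp_c`) and the true state (`core_temp_c`), so
controller performance can be judged on the physical temperature rather than
on sensor noise.

What the generator does **not** emulate: redistribution hypothermia dynamics
after induction (only an initial-condition offset), skin–core gradients,
multi-compartment heat flows, vasomotor feedback, and any subject-specific
insulation differences. Tests passing on this plant therefore demonstrate
closed-loop correctness and robustness of the algorithm against a plausible
thermal load — not clinical performance on real patients.

## Trial evaluation

A trial recording is a strictly time-ordered 1 Hz series of measured
temperature and concurrently active setting. The metrics follow once-a-second
accounting: each present sample contributes one second (gaps contribute
nothing), a sample is outside a band when $|T - T_{tar}|$ exceeds the
tolerance, and the within-band percentage is $100\,(1 - \text{outside} /
\text{total})$ rounded half-up to two decimals — the rule that reproduces all
published per-trial table entries from their integer second counts. Setting
adaptions are counted as recorded state transitions between consecutive rows,
with the rate normalized per hour of recording. The 120 s sliding median
(`sliding_median()`, centered, partial windows at the edges) is a display
filter for suppressing flush artifacts; the tables are computed on raw
readings, with a `filtered` flag available for sensitivity analysis.

`replay_controller()` feeds a recording's temperatures through the algorithm
and compares predicted against recorded settings second by second. A trial
generated by this package replays at 100 % agreement under its own
configuration — the loop's end-to-end consistency check — and diverges under
a different scaling factor, which is what makes replay useful as a
configuration forensic.

## Problem sizes and determinism

The test suite runs closed-loop simulations of 6 h at 1 Hz (21 600 steps)
over a robustness grid of mass 30–60 kg and fever power 0–2× default, a 24 h
uncontrolled run (the fever needs about half a day to develop), and
oracle-equivalence checks on one hundred 10 000-sample random streams; the
acceptance script simulates the full 90 h trial. All randomness flows through
explicit integer seeds: a fixed seed reproduces a trial byte-for-byte,
including its CSV serialization, and every written file carries label, seed
and generator version in its metadata header.

## Known limitations

* The plant is a single linear compartment with invented coefficients; it is
  a test harness for the loop, not a calibrated thermophysiological model.
* The serial emulator models frames and presses, not electrical behavior,
  timing jitter or fault injection; the protocol has no checksums.
* Replay assumes the recorded settings reflect the device state at the
  recorded second; command-to-state latency of a physical unit would shift
  agreement at change instants.
* The evaluation-clock phase of the original system relative to trial start
  is unknowable from a recording; replayed change counts on real recordings
  are therefore comparable rather than bit-exact.
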
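---
title: "Breach kinematics and energetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breach kinematics and energetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalebreach)
```

Breaching — a whale launching part or all of its body clear of the water —
is among the most energetically extreme burst behaviors in any vertebrate.
`whalebreach` reconstructs what happens under water before the leap from
biologger records (depth, three-axis acceleration, three-axis magnetics),
and prices the maneuver with a hydrodynamic work model. This vignette
documents the models, their assumptions, every tunable that matters, and
the design decisions taken where more than one defensible choice existed.

## Tag processing

Raw tag streams are represented as a `sensor_frame`: a uniform time grid
at a known rate (5–400 Hz), depth in meters positive down, acceleration in
units of g on surge/sway/heave axes, and magnetics in arbitrary units.
All filtering is zero-lag: a 2nd-order Butterworth is applied forward and
backward (effective 4th order), so filtered features stay aligned in time
with the raw record — essential when the quantity of interest is *when*
something happened. The Butterworth order is not a literature-prescribed
value; 2nd order applied twice is the common choice in biologging work and
is exposed in the configuration. Edges are handled by point-reflected
padding sized to at least three cutoff periods.

High-pass signals are always computed as the *residual* of the matching
low-pass (`x - lowpass(x)`), so any low/high decomposition is exactly
additive by construction.

Orientation follows the standard accelerometer/magnetometer framework
under the quasi-static assumption: accelerometer and magnetometer channels
are smoothed at 1 Hz, pitch is the arcsine of the negated surge specific
force over the acceleration norm, roll comes from the sway/heave pair, and
heading from tilt-corrected magnetics. Roll is reported undefined wherever
|pitch| ≥ 80° (gimbal lock). Pitch is then split at 0.2 Hz into *body
pitch* (the posture of the animal) and *fluke pitch* (the oscillation
imposed by tail beats).

Two independent speed estimates are available:

* **Orientation-corrected depth rate** — `|d(depth)/dt| / |sin(pitch)|`,
  valid only above 30° of pitch; shallower samples are masked, not
  guessed.
* **Jiggle speed** — the RMS of high-frequency (10–45 Hz) accelerometer
  vibration grows with speed through the water; a deployment-specific
  log–log regression against valid depth-rate speeds maps vibration level
  to speed. Estimates outside the calibrated speed range are clamped and
  flagged: above it accelerometers may clip, below it the vibration
  drowns in the noise floor.

## Breach detection and per-breach metrics

A breach is found as a surfacing (depth ≤ 0.1 m; the 0.1 m allows for
sensor noise) preceded by a rapid ascent (mean vertical speed > 0.8 m/s
over the prior 2 s). The exit is the first surface sample with positive
body pitch. The start of the maneuver is the *later* of two signatures:

1. the last upward zero-crossing of body pitch before the exit — the
   moment the body pitched past horizontal and began the ascent; and
2. the onset of intensified fluking, for breaches begun while the whale
   was already ascending.

The fluking-onset signal needed care. Zero-phase filtering smears a step
in body pitch two to three seconds *backwards* into the high-pass (fluke)
band, which would trip a naive RMS threshold well before the burst.
Three guards make the onset reliable: the fluke signal is re-high-passed
at 0.2 Hz before the RMS (removing sub-band leakage), the RMS uses a
trailing rather than centered window, and the onset must both clear
`max(2 × the deployment's 20th-percentile RMS, 0.5 × the ascent's own
90th-percentile RMS)` and stay above that level for most of the following
3 s. When neither signature fires, the ascent onset itself is used and
the segment is flagged low-confidence rather than silently guessed — the
analyst, not the code, should arbitrate those.

Exit speed is estimated by fitting the vertical rate over the final
ascending ~1.5 s (a quadratic when the pitch is still developing, as in a
late pitch-up; otherwise a line), evaluating the fit at the exit, and
dividing by the sine of the *settled* exit pitch (the median over the
0.6 s after the exit, where the filters are no longer averaging the ramp).
Simpler estimators — the median of the pointwise speed ratio over the last
second — are biased low for accelerating exits and high by up to 20% for
fast late pitch-ups, which is why the package does not use them. When the
exit pitch is below 30° the depth-rate method is invalid and the
calibrated jiggle model is used instead.

Fluke strokes are counted as zero-crossings of the fluke-pitch signal:
one stroke per pair of same-direction crossings, i.e. `(m − 1)/2` full
cycles for `m` crossings. The trailing half-stroke at the water exit is
thereby dropped, and a partial leading cycle is added as a fraction of
the median stroke period. Samples lying numerically on zero are treated
as crossings so that cycle boundaries landing on the grid are not
absorbed.

Trajectory shapes are labelled by rules evaluated on the 16 s before the
start (thresholds all in `kin_config()`): station-holding at depth then a
direct ascent (**I**); a slow (< 0.5 m/s) unpowered ascent before the
burst (**J**); a descent of ≥ 3 m from a surfacing within 30 s,
immediately reversed into the breach ascent (**V**); a shallow (< 5 m)
near-horizontal run before a final pitch-up (**U**); otherwise
unclassified. The I/J signature window stops 1 s short of the start
because the zero-phase filters smear the burst backwards.

## The emergence model

The whale is modelled as a uniform, neutrally buoyant cylinder of length
$L$ leaving the water along a straight path at angle $\theta$ with speed
$U$. Once a fraction $E$ of the cylinder is emerged, that fraction's
weight is unsupported, giving an along-path deceleration $g E \sin\theta$;
integrating to the apex yields

$$E = \frac{U}{\sqrt{g\,L\,\sin\theta}}.$$

Drag and thrust during the emergence are ignored, and the fraction is
capped at 1.2 (whales have been observed clearing the water by ~120% of
body length). A breach is "full" when strictly more than 40% of the body
emerges. Two consequences worth noting: the model depends on length and
not at all on mass — length, not weight, is the obstacle to breaching —
and the minimum speed for a given emergence scales as $\sqrt{L}$.
Classical photographic estimates of minimum 40%-emergence speeds
(1.8 m/s for a 6 m calf, 2.5 m/s for a 12 m adult) sit ~20% below this
cylinder model but share the $\sqrt{2}$ length ratio; the original
formulation likely credited thrust until fluke exit. The model is a
plain function, so an alternative can be substituted wherever an
emergence fraction is consumed.

## The energetics model

The cost of the underwater acceleration (costs after breaking the surface
are excluded) is mechanical work against three sinks, divided by
efficiency factors:

$$W_{metab} = \frac{1}{\eta_{metab}\,\eta_{prop}}\left[
  \tfrac12 M (U_f^2 - U_i^2) + \tfrac12 k M (U_f^2 - U_i^2)
  + W_{drag,acc} + W_{drag,plat}\right]$$

with a linear speed ramp from $U_i$ to $U_f$ over $T_{acc}$ and an
optional constant-speed plateau. Friction drag uses the airship-derived
coefficient $C_D = \tilde F\,[0.072\,Re^{-0.2}]\,[1 + 1.5 r^{1.5} + 7
r^{3}]$ (r = width/length) referenced to the allometric wetted area
$S_{wet} = 0.08\,M^{0.65}$, valid for $Re > 10^6$ (a warning, not an
error, below that). Integrating the drag power over the ramp gives the
closed form implemented in `work_drag_acceleration()`; the test suite
checks it against trapezoid quadrature of the underlying integral at
1 ms steps to 0.1%. As $U_i \to U_f$ the closed form reduces
continuously to the plateau expression, which is handled explicitly to
avoid 0/0.

Parameters, defaults, and provenance:

| parameter | default | meaning |
|---|---|---|
| $\rho_w$ | 1027 kg/m³ | seawater density |
| $\nu$ | 1.0e-6 m²/s | kinematic viscosity; seawater spans 1.0–1.4e-6 over relevant temperatures, and results move < 7% across that range ($C_D \propto \nu^{0.2}$) |
| $\tilde F$ | 2 | drag amplification for the heaving body and tail (1–3 plausible at $Re \sim 10^7$) |
| $k$ | 0.045 | added-mass coefficient of a whale-shaped body |
| $\gamma$ | 1 | wave-drag factor; excluded by default because breaching ascents are steep, exposed for near-surface horizontal maneuvers |
| $\eta_{metab}, \eta_{prop}$ | 0.25, 0.75 | metabolic and propulsive efficiency |
| muscle fraction | 0.132 | locomotor muscle as a share of body mass |

Buoyancy is set to zero (neutral buoyancy assumed); body mass is derived
from length by a species power law rounded to the nearest 1000 kg. The
shipped humpback coefficients are a log–log fit to the five reference
(length, mass) pairs used by the reconstructions, because the original
whaling-data regression constants are not among this package's inputs;
users with published coefficients can override the registry. No single
power law can reproduce all five reference masses after rounding (two
different lengths share one printed mass); the fit reproduces four.

Power metrics: average muscle power is $W_{metab}\,\eta_{metab}$ over the
event duration; peak power is evaluated over the final second of the
ramp, where drag and acceleration are both maximal. Reported outputs are
rounded half-away-from-zero to two significant figures — masses are only
known to the nearest tonne — while all internal computation is full
precision.

Daily-budget context uses two allometric field-metabolic-rate laws
bracketing what is known for large cetaceans: a marine-mammal law
$3511\,M^{0.45}$ kJ/day (low FMR, makes breaching relatively expensive)
and a terrestrial law elevated by 50%, $1.5 \times 2.25 \times
(1000\,M)^{0.808}$ kJ/day. The second is dimensionally ambiguous as
usually quoted; only the grams-inside-the-power-law reading produces an
upper bound consistent with the published 0.08–0.20% relative costs, so
that reading is implemented. Which law applies to large whales is an
open question, so both percentages are always reported.

## The synthetic-data generator

Real breach deployments are not redistributable, so the package ships a
generator that renders ground-truthed trajectories of the four canonical
approach shapes into sensor streams. Its defaults emulate the envelopes
observed in tagged humpback whales: start depths of 2–30 m depending on
shape, exit speeds 2.8–7.5 m/s, exit pitches 38–72°, stroke frequencies
0.3–0.6 Hz, occasional rolled exits; accelerometer white noise of 0.02 g;
and a speed-dependent vibration ("jiggle") band at 10–45 Hz whose RMS
follows $0.02\,U^{1.5}$ g, split evenly across axes. The exponent is a
choice, not a measurement — any monotone law supports calibration — and
is configurable. Fluke strokes appear as a pitch sinusoid, tapered out
over the final 0.4 s so the exit state is exact; heading is constant per
breach; sensors follow the quasi-static gravity model.

What the generator deliberately does *not* emulate: specific-force
contributions of the body's own acceleration, wave motion at the surface,
tag slip, depth-sensor noise, or hydrodynamically faithful flow noise.
Passing the recovery tests therefore demonstrates that the pipeline
inverts its stated sensor model to tolerance (speeds within 5%, start
times within ~1 s, start depths within 0.5 m, shape labels ≥ 90%
correct), not that it is robust to every artifact of real deployments —
the same caveat any simulation-validated biologging pipeline carries.

## Numerical choices and degenerate inputs

* Ascent durations in the generator are solved by bisection so the
  trajectory reaches the surface exactly; the integrated depth profile is
  rescaled (by a factor within 0.1% of unity) to end at 0 exactly.
* `work_drag_acceleration` switches to the plateau limit when
  $|U_f - U_i|$ is below $10^{-9}\max(U_f, 1)$.
* Filters refuse cutoffs at or above Nyquist; decomposition requires
  ≥ 10 s of data; stroke counting requires ≥ 1 s segments and returns
  (0, 0) when no crossings exist.
* Emergence errors on non-positive pitch rather than returning a
  complex-valued fiction; speeds/masses/lengths are validated positive.
* All random draws flow from one seeded generator per synthesis call, and
  the caller's RNG state is restored afterwards; identical seeds give
  bit-identical frames.

## Problem sizes

The test suite and reproduction script run on synthetic deployments of
4–20 breaches at 25 Hz (a few hundred seconds of record each) and single
400 Hz breaches for vibration calibration — a few seconds of compute in
total. The energetics reconstructions are closed-form and instantaneous.

## Known limitations

Besides the generator caveats above: breach starts that the original
analysts located manually are here located by fixed rules with a
low-confidence flag rather than judgment; the jiggle calibration slope is
attenuated by the sensor noise floor at low speeds (about −9% at 0.02 g
noise), so calibrations should prefer fast, steep reference segments; the
emergence model ignores drag and thrust during emergence; and the
energetics model prices only the approach phase — nothing after the body
breaks the surface, and no engulfment costs for feeding lunges.
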
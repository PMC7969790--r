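---
title: "Models and methods behind equigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind equigait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

`equigait` studies one question: when gait variables are extracted from
extremity-mounted inertial sensors on trotting horses, how much of the
variation between measurements is biology (the horse) and how much is the
measurement chain (the evaluator operating the software, and the repeated
analysis of the same recording)? This vignette documents the models the
package implements, the defaults it ships, and what its simulations can
and cannot say about real recordings.

## 1. The signal model of the session simulator

Six sensors are simulated per horse: metacarpal left/right, metatarsal
left/right, tibial left/right. The sensor frame is right-handed with x
along the lateromedial axis (rotation about x is sagittal-plane motion),
y craniocaudal (rotation about y is coronal motion) and z proximodistal;
gravity is (0, 0, −1) g at zero tilt.

Over one stride cycle, a segment's sagittal angle is a phase-warped
two-harmonic cosine,

$$\theta(u) = \tfrac{R}{2}\left[\cos 2\pi w(u) + h \cos 4\pi w(u)\right],$$

where `u` is the cycle fraction, `R` the programmed range of motion in
degrees, `h` the second-harmonic weight and `w(u)` a piecewise-linear
circular warp that places the maximum at the programmed protraction event
and the minimum at the programmed retraction event. Two properties make
this family convenient:

* for `h ≤ 1/4` the extrema stay exactly at `w = 0` and `w = 1/2`, so
  the range of motion is exactly `R` and the events are exactly where
  they were programmed, in closed form;
* the gyroscope channel is the analytic derivative of `θ`, so numerical
  integration of the simulated stream recovers the programmed angle, and
  a pure sinusoid (`h = 0`, events half a cycle apart) obeys the textbook
  amplitude relation `ω_max = π f R`.

Each limb's waveform is a time-shifted copy of a common shape: a limb
reaches maximal retraction at its phase (the left hind, which defines the
stride zero point, at 0) and maximal protraction a common `swing_offset`
later. This is deliberate — circular cross-correlation identifies the lag
between two cycles exactly when they are shifted copies, so the programmed
phases are recoverable without bias. Horses differ in stride duration,
phases, swing offset and ranges of motion; the swing offset varies
between horses but not between limbs, preserving the shifted-copy
structure.

Sessions follow the recorded protocol structure: a 10 s standstill (the
gravity calibration window), an optional walk segment, an acceleration
ramp whose stride durations interpolate linearly into steady trot, the
steady trot itself (default 25 strides; field recordings collect a
minimum of 20), a deceleration ramp and optional trailing walk. Walk uses
near-evenly spaced limb phases (0/25/50/75%), a 1.1 s stride and reduced
ranges of motion. Motion begins a quarter cycle before the first
zero-point event so the first retraction extremum is approached from a
descending flank. Sensor imperfections are additive iid Gaussian noise
per sample and channel plus an optional constant gyroscope bias; there is
no hoof-impact transient, no magnetometer and no biomechanical forward
dynamics.

Default kinematics (stride 0.731 s; phases 63.1/13.7/49.5% for LF/RF/RH;
hock sagittal ROMs 42.1/37.2°; fore-cannon sagittal ROMs ~85°) are typical
sound-horse treadmill trot values, and the between-horse standard
deviations mirror the spread reported for such cohorts. The hind-cannon
sagittal ROM and the tibial coronal ROM are not part of the analysed
variable set and their defaults (60° and 8°) are package choices.

## 2. The extraction chain

`extract_record()` runs, in order:

1. **Calibration** — initial tilt from the mean accelerometer vector over
   the standstill (`atan2` of the gravity components), gyroscope bias as
   the mean angular velocity over the same window. The window must span
   at least one second; a mean acceleration far from 1 g is an error.
2. **Integration** — cumulative trapezoidal integration of the
   bias-corrected rotation velocities, started from the calibrated tilt.
3. **Segmentation** — stride zero points are the per-cycle minima of the
   left hind metatarsal sagittal angle (maximal retraction). Detection is
   a local-extremum search on a lightly smoothed copy, keeping only
   minima below the signal midrange and thinning to half the median
   candidate spacing (deepest first); the standstill region is excluded.
   Each boundary is then refined to sub-sample precision by a quadratic
   fit, because one sample at 102.4 Hz is 1.3% of a trot stride — more
   than the precision the event timings need.
4. **Window selection** — the longest contiguous run of strides whose
   stride-duration coefficient of variation is at most `cv_threshold`
   (default 0.05), with residual ramp strides trimmed from the run edges;
   at least `min_strides = 5` strides are required, otherwise selection
   fails (this is the canonical minimum for representative kinematics).
   Manual windows are validated, not searched.
5. **Representative stride** — the stride minimising the summed squared
   difference against all other strides of the window, pooled over the
   six lateromedial velocity cycles resampled to a 100-point grid. Ties
   go to the lowest index, as do all argmax/argmin ties in the package.
6. **Phasing** — circular cross-correlation of each limb's velocity cycle
   against the left hind cycle; the phase is the argmax lag in percent of
   stride, reported at the 1% grid resolution. The recovered pattern also
   classifies the gait (trot: diagonal pairs synchronised and half a
   stride apart; walk: four near-evenly spaced events). A window that is
   not steady trot is an error.
7. **Event timing** — protraction/retraction extrema of each segment's
   sagittal angle, located on the sampled series and refined by a
   quadratic fit, expressed in percent of stride between the refined
   boundaries. Late-cycle protraction is recoded (98% → 2%). Event
   positions within 2% of the cycle end are folded onto the origin so a
   variable pinned at the stride boundary stays continuous.
8. **Ranges of motion and symmetry** — per-stride max-minus-min of the
   integrated angle after an endpoint-pinned linear detrend (subtracting
   the line through the stride's boundary values), averaged over the
   window. This detrend is exact for periodic signals — it changes a
   noise-free ROM by nothing — while removing the linear drift a
   residual gyroscope bias produces. Hock symmetry is the absolute
   left-right difference over the mean, in percent; the sign is not
   retained.

Numerical choices worth knowing: percentages live on a circular [0, 100)
scale and tests compare them circularly; the cross-correlation operates
on demeaned cycles and a zero-variance cycle is an error; a flat angle
cycle (no events) is an error; all percent-of-stride quantities except
the phases carry sub-grid precision from the quadratic refinements.

## 3. The reliability model

For each surface separately and each of the 19 analysed variables, the
response is modelled as

$$Y_{ijk} = \mu + \alpha_i + \beta_j + \varepsilon_{ijk},$$

evaluator `i = 1..I` (default 6), horse `j = 1..J` (default 10),
repetition `k = 1..K` (default 3, giving n = 180 rows). The balanced
closed-form sums of squares (horse, evaluator, remainder pooled into
error with df `n − 1 − (I−1) − (J−1)`) give the mean squares; they agree
with `stats::aov` on the additive model and with an explicit triple-loop
oracle to 10 decimal places in the test suite.

Variance components come in two conversion modes:

* **`"paper"`** (default): `σ²_H = (MS_H − MS_E)/10`,
  `σ²_Ev = (MS_Ev − MS_E)/6`, `σ²_R = MS_E` — the divisors as printed in
  the methodological source this package follows, which are the numbers
  of horses and evaluators;
* **`"balanced"`**: divisors `I·K = 18` and `J·K = 30`, the
  expected-mean-square solution for the balanced crossed design, under
  which the estimators are consistent (the parameter-recovery tests use
  this mode).

Whether the printed 10 and 6 are intentional or a typographical slip of
the source cannot be resolved from its text, so both behaviours are kept
behind the `mode` flag; the two modes are monotonically related, so
orderings of ICCs are unaffected. Negative component estimates are
truncated to zero before any ratio is formed — standard practice the
source is silent about.

From the (truncated) components: `ICC_inter = σ²_H / total`,
`ICC_intra = (σ²_H + σ²_Ev) / total`, and the three VPCs are the
components over the total. Algebraic consequences — VPCs sum to one,
`vpc_horse = icc_inter`, `icc_intra ≥ icc_inter`, everything in [0, 1] —
are enforced property-style in the tests. A variable with zero total
variance has undefined ICC/VPC; `reliability_report()` records the fact
and keeps going.

The evaluator-experience model nests evaluator within experience type
while horses remain crossed: the per-evaluator means (over `J·K`
observations; the shared horse terms cancel in every evaluator contrast)
feed a one-way F-test of type against between-evaluator-within-type
variation on `(T−1, I−T)` degrees of freedom. Under the null this is an
exact F-test, which the calibration test confirms (rejection rate at
α = 0.05 within [0.03, 0.07] over 1000 simulated tables). The source's
model notation is ambiguous about this nesting (horses are crossed with
type, not nested in it); evaluator-in-type is the only design-consistent
reading. No multiple-testing correction is applied across the 19
variables, matching the analysis this package mirrors. Descriptives are
mean, sample SD, median and IQR with linear-interpolation quantiles
(type 7; configurable, since the original software's convention is
unknown).

## 4. The gait-variable table simulator

`simulate_gait_table()` draws directly under the additive model:
evaluator effects `N(0, σ²_Ev)`, horse effects `N(0, σ²_H)`, residuals
`N(0, σ²_R)`, plus an optional additive shift for experienced
evaluators. The default grand means are the typical sound-horse values
above. The source reports only total between-horse spreads, not a
decomposition into components, so the default partition is a package
choice: horse 92%, evaluator 2%, repetition 6% of each variable's
variance, with the horse component anchored to the squared between-horse
SDs — the regime of a highly reliable system where nearly all variation
is biological. Every draw is seeded; one user seed is expanded by a
counter-based scheme into independent sub-streams per surface, variable
and sensor stream, so identical specifications are bit-reproducible and
independent of evaluation order.

## 5. Study orchestration

`run_study()` reproduces the blinded design end to end: one kinematic
profile per horse; one session per horse and surface; each session copied
(default three times) and hidden behind shuffled zero-padded ids, the key
kept aside; every evaluator extracts every blinded dataset; the table is
unblinded and analysed per surface. Evaluators are emulated as window
choices: each has a habitual preferred window length and position within
the steady run (drawn once per evaluator), jittered per dataset. This
models "evaluators may choose different windows within the same trot
segment" mechanically; it is a stand-in, not a claim about how human
choices actually differ. With all evaluators forced to the same window,
the evaluator variance is exactly zero and the two ICCs coincide — a
degenerate-design check in the test suite.

The default run (3 surfaces × 10 horses × 3 copies × 6 evaluators = 540
extractions) takes well under a minute because the evaluator-independent
work — calibration, integration, segmentation, cycle resampling — is done
once per session by `prepare_session()` and shared across copies and
evaluators, which is also how the blinded copies behave in reality
(identical processed data).

## 6. What the simulations do and do not show

The simulator provides exact ground truth, which is what makes the
pipeline testable: noise-free sessions must return the programmed phases
to within 1% of stride, stride duration to within one sample, ranges of
motion to within 2%, and parameter-recovery runs must return the
variance components that generated the tables. Passing those tests says
the implementation is faithful to its models. It does not say the models
capture real horses: real trot has hoof-impact transients, soft-tissue
oscillation, inter-stride variability far richer than iid noise, drift
that is not a constant bias, and evaluator behaviour that is not a seeded
window habit. Reliability numbers from `run_study()` therefore
characterise the pipeline under its own assumptions — they are not
predictions of field ICCs, and reported field values are not reproducible
from this package because the underlying recordings are not public.

Two structural caveats of the package's self-consistent event convention:
the left hind retraction timing is pinned at the stride zero point by
definition (so that variable carries no between-horse signal in
simulated studies), and all event timings are expressed relative to the
session zero point rather than any per-limb reference an external
software might use. Phases are reported at the 1% cycle-grid resolution,
which bounds the phasing ICCs attainable in simulation when the true
between-horse phase spread is of similar size (about 1%).
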
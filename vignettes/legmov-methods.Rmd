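---
title: "Detecting full-day infant leg movements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting full-day infant leg movements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legmov)
```

`legmov` counts infant-produced leg movements in full-day recordings from
ankle-worn inertial sensors and relates daily movement rates to the age of
walking onset. This vignette is the package's own account of the method:
the detection rules and their assumptions, every tunable that matters, the
synthetic-data generator used to test the pipeline, and the numerical
conventions a reimplementer would need.

## 1. Signal model and preprocessing

Each leg contributes six channels at 20 Hz: linear acceleration per axis
(m/s²) and angular velocity per axis (rad/s). Because a limb movement can
project onto any axis, all detection operates on the per-sample Euclidean
norms of the two triples, which are invariant to how the sensor happens to
be oriented on the ankle.

The acceleration magnitude sits near the gravity norm (≈ 9.81 m/s² at
rest) and drifts slowly over hours. A single least-squares line over the
*entire* wear period is subtracted, putting the baseline at 0 so that
movement appears as signed deviations around zero. Two consequences worth
stating:

* detrending is idempotent and removes any affine-in-time component, so a
  constant gravity offset plus linear drift vanishes exactly;
* one global line assumes drift is approximately linear across the day. A
  recording with strongly nonlinear drift would leave a wandering baseline;
  the package deliberately does not low-pass filter or window the detrend by
  default, keeping the preprocessing to a single documented pass.

The gyro magnitude is left raw. It is only ever compared against a floor
(`gyro_floor`, default 0 rad/s), and — unlike the acceleration — its
baseline is never referenced by the segmentation rules, so detrending it
would change nothing downstream while making the "rotation present"
condition harder to reason about.

## 2. Adaptive threshold calibration

The smallest acceleration peaks that reflect movement rather than noise are
consistent within a recording but vary between recordings, spanning roughly
1.00–3.25 m/s² in absolute magnitude. Calibration therefore collects, over
the whole wear period (sleep included):

* positive local maxima of the detrended magnitude with values in
  `[band_low, band_high]` = [1.00, 3.25] m/s² (endpoints inclusive), and
* negative local minima with values in the mirrored band.

Each side's threshold is `mean − sd` of its in-band peak values (sample
standard deviation, n − 1). The negative side is computed on absolute
values and negated, so both thresholds lie *between* the baseline and the
peaks; the alternative signed convention (`mean + sd` of negative values)
would be equivalent under mirror symmetry, and the mirrored form was chosen
because it makes the two sides exactly symmetric: negating the signal swaps
the two thresholds, a property the test suite checks.

Conventions and degenerate cases:

* A peak is a strict local extremum over three samples; an exact plateau
  (equal consecutive values) counts once. At 20 Hz this is the simplest
  reproducible reading of "peak".
* An empty in-band peak list on either side is a calibration failure, not a
  silent default — the error carries the band occupancy so the user can
  widen the band or supply thresholds manually.
* One peak on a side uses sd = 0 with a warning.
* If `mean − sd ≤ 0` the threshold clamps to `band_low / 2` with a warning.
  This cannot arise from in-band peaks (for values in [1, 3.25] the
  Bhatia–Davis bound keeps `mean − sd` positive) but guards direct calls
  with arbitrary peak lists.

## 3. Movement segmentation

A movement **starts** at the first sample where the detrended acceleration
magnitude exceeds the positive threshold *or* drops below the negative one,
with rotation simultaneously present (`gyro_mag > gyro_floor`). Starting on
either side was chosen because calibration computes both thresholds and
excursions of both signs initiate movements in real data; requiring the
positive side only would halve the trigger opportunities for biphasic
movements.

A movement **ends** when two baseline crossings in *different* directions
(one positive-to-negative, one negative-to-positive, either order) have
occurred after the start. Each pause or change of direction of the limb
therefore closes one movement and a new exceedance starts the next: a kick
of flexion then extension is two movements.

Discrete-sample conventions, each of which the brute-force reference
implementation transcribes literally:

* A crossing occurs between samples `k`, `k+1` when both signs are nonzero
  and differ. Exact-zero samples inherit the previous nonzero sign, so a
  graze of the baseline is not a crossing — this avoids double-counting.
* Crossings are counted from the start sample onward ("after" the start:
  the pair beginning at the start sample is the earliest that can count).
* The event's end index is the later sample of the pair completing the
  second qualifying crossing; scanning resumes at the *following* sample,
  so no sample belongs to two events and events cannot overlap.
* If the recording ends before the second crossing, the open event is
  discarded and reported in diagnostics: an unverifiable movement is not
  counted.
* No refractory period and no maximum event duration are imposed.

Because the zero-inherited sign sequence alternates at every crossing, two
consecutive crossings after the start are automatically of opposite
direction; the fast implementation exploits this (the end is simply the
second crossing at or after the start), while the reference tracks the
up/down flags explicitly. Their agreement over thousands of randomized
signals is a standing test.

The gyro gate is what rejects background motion: cars, strollers and
mechanical swings produce oscillatory *linear* acceleration with virtually
no rotation at the ankle, so with `gyro_floor = 0` and a truly rotation-free
signal, no event can start regardless of acceleration amplitude. Real gyros
are noisy; `gyro_floor` is exposed for sensitivity analyses, and raising it
can only remove events. What the gate cannot reject is parent handling
(diaper changes, dressing): those movements involve real rotation and are
counted — a documented limitation of the approach, mitigated only by their
small number relative to tens of thousands of infant-produced movements.

## 4. Awake-time normalization

Daily counts are comparable across infants only after normalizing by awake
time. The parent activity log contributes half-open clock intervals; total
logged sleep overlapping the wear interval is rounded to the nearest
10 minutes (the realistic precision of a parent log) and subtracted from
the wear duration. Unlogged time counts as awake, so a missing log means
awake = wear. Movements detected during logged sleep still enter the count
— an infant who wakes briefly and moves has genuinely moved — sleep enters
only through the rate's denominator. A wear period that is entirely asleep
has no defined rate and errors rather than returning infinity.

## 5. Validation scoring

Two modes are provided:

* **Segment counts** (the fidelity mode): ground truth is an observer's
  movement count per scored interval per leg. Detected events are assigned
  to segments by start time; per segment, `over = max(0, det − obs)`,
  `under = max(0, obs − det)`, `correct = min(det, obs)`; sensitivity is
  Σcorrect / Σobserved. This mirrors validation against video, where an
  observer can count movements but cannot count non-movement, which is why
  specificity is undefined and not reported.
* **Event times** (the stricter simulator mode): greedy one-to-one matching
  in time order within ± a tolerance. In the package's own property tests
  the tolerance is 1.0 s — one maximum movement duration — because the
  detector's start sample may legitimately fall anywhere within a movement
  (it triggers on whichever lobe first exceeds a threshold), so a window
  tighter than the movement itself conflates timing offsets with misses.

With the tolerance taken to infinity, event matching degenerates to
min-count bookkeeping and reproduces the segment totals on a single
segment, which ties the two modes together and is tested.

## 6. The synthetic-data generator

No raw sensor recordings are distributable, so the package ships a
generator whose output exercises every branch of the pipeline with known
ground truth. Per leg it builds, at 20 Hz:

* **Resting signal**: white noise per axis (`noise_sd`, default
  0.15 m/s²), with gravity (9.81 m/s²) plus a slow linear drift
  (`drift_slope`, default 0.2 m/s² per hour) on the vertical axis.
* **Movement complexes**: Poisson arrivals (`burst_rate`, default 12
  complexes/min) outside naps, with a dead time of one mean movement
  duration between complexes so ground truth stays unambiguous. Each
  complex holds `k` movements (`direction_changes`, uniform on 1–4); each
  movement is a biphasic excursion — two half-sine lobes of opposite sign —
  with lobe signs alternating strictly through the complex, so every
  movement yields exactly one up- and one down-crossing. Movement durations
  are uniform on 0.3–1.0 s, and consecutive movements are separated by
  brief pauses (0.05–0.25 s), matching the very small no-movement gaps an
  observer cannot resolve but a 20 Hz sensor can. Excursions ride on the
  gravity axis so the magnitude signal deviates to both sides of baseline,
  exercising both thresholds.
* **Amplitudes**: lobe amplitudes are drawn from a truncated exponential on
  1.5–3.0 m/s² with decay 2 per m/s² (`burst_amplitude_decay`; 0 recovers
  a uniform draw). The bottom-heavy shape mirrors real recordings, where
  most movement peaks crowd the lower edge of the calibration band and the
  mean-minus-sd thresholds land just above it. Note a structural fact of
  the calibration rule: for *any* bounded amplitude distribution,
  `mean − sd` cannot fall below the distribution's minimum, so a calibrated
  threshold necessarily sits inside the amplitude range rather than below
  it; movements whose two lobes both fall below the threshold are the
  detector's intrinsic misses.
* **Rotation**: one gyro half-sine (`gyro_burst_amplitude`, 1.0 rad/s) on a
  randomly chosen axis spans each complex, so every injected movement has
  concurrent rotation.
* **Background motion**: optional swing segments add a pure sinusoid on the
  gravity axis with *zero* added rotation (an optional `gyro_leak` lets
  tests probe the gyro floor); optional naps suppress complexes and are
  written to the generated activity log.

A single seeded RNG stream drives each call (left leg fully, then right),
so runs are bit-identical under a repeated seed.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: biomechanically realistic limb trajectories,
orientation dynamics (gravity is pinned to one axis), sensor saturation and
nonlinearity, gyro noise, parent handling, and the true day-scale
nonstationarity of infant behaviour. The synthetic tests establish that the
*rules* are implemented correctly and that the pipeline's statistical
bookkeeping is sound, not that the published detection accuracy transfers
to any particular real recording.

### Default rates

At the defaults (12 complexes/min × 2.5 movements/complex) the generator
produces roughly 1800 movements per awake hour, the middle of the
1000–4000 range observed in full-day infant recordings. Test and
acceptance runs use 5–10-minute recordings (6 000–12 000 samples per leg),
long enough for a few hundred movements per leg — the scale at which the
5% count-recovery property is meaningful — while keeping the whole suite
fast.

## 7. The walking-onset model

The per-visit table (12 infants × 3 visits) carries each infant's walking
onset (days at the first three independent steps, constant across the
infant's rows) and the mean-of-legs movement rate per awake hour. The model
is

`onset = β₀ + β₁ · rate (+ γ · covariate) + ε`,

with visit as a repeated measure under a *diagonal* covariance structure:
residuals independent across all rows, variance depending only on the visit
number (no random effects, no within-infant correlation — the literal
reading of the named structure). Estimation is by REML through
`nlme::gls(weights = varIdent(~ 1 | visit))` with a tightened convergence
tolerance (1e-10); covariates (age in months, AIMS raw score, or a
user-supplied length-for-age percentile) are modelled one at a time, the
appropriate choice at n = 12 infants. Inference uses Wald t-tests with
residual degrees of freedom at α = 0.10; other degrees-of-freedom
conventions (e.g. Satterthwaite) are not asserted, and the full coefficient
table is exposed via `tidy()` so any convention can be applied downstream.

```{r model}
fit <- fit_onset_model(study_visits())
tidy(fit)
visit_variances(fit)
interpret_slope(fit, 1000)
```

Two grounding checks are built into the tests: tying the visit variances
(`equal_variances = TRUE`) must reproduce the ordinary least-squares slope
to 1e-8, and simulating outcomes from the fitted model class and refitting
must recover the slope within two standard errors in ≥ 90% of replicates.
A perfectly constant outcome makes the variance components zero and the
GLS problem singular; the fit then falls back to the trivial solution
(slope exactly 0) rather than failing.

Length-for-age percentiles are accepted only as user-supplied numbers: the
package does not compute them from growth charts, which would drag in an
external reference dataset.

## 8. Reporting conventions

* Printed integer summaries (daily counts, rates, summary-row means and
  sds) round halves *away from zero*, matching how such tables are
  conventionally typeset; base R's `round()` rounds halves to even.
* Validation sensitivity is reported to the nearest percent; segment rates
  to one decimal in movements/s; model coefficients to three decimals.
* Recording times are seconds from wear start; logs use clock timestamps,
  mapped onto the recording axis through the wear interval. All intervals
  are half-open `[start, end)`, partitioning the day without double
  counting.

## 9. Known limitations

* Parent-handling motion is counted as movement (real rotation is present);
  this is inherent to the detection rules.
* A single global detrend assumes day-scale drift is linear.
* The gyro floor defaults to the literal 0, which on real (noisy) gyro
  hardware makes the rotation gate permissive; a small positive floor is
  the practical remedy and its effect is monotone by construction.
* Movement-type classification, bilateral phase structure, and posture
  inference are out of scope.
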
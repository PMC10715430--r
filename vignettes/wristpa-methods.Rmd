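---
title: "Computing physical activity endpoints from raw wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing physical activity endpoints from raw wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristpa)
```

## Overview

`wristpa` turns multi-day raw tri-axial wrist accelerometer recordings
(gravitational units, fixed sampling rate, optionally with a near-body
temperature channel) into daily physical activity endpoints, and provides
the statistical layer used to compare two processing methods or two
participant groups. The processing chain is:

1. **Autocalibration** — per-axis gain and offset estimated from rest
   periods.
2. **Non-wear detection** — acceleration variance plus temperature level
   and rate of change; an accelerometer-only fallback exists.
3. **Sleep-window estimation** — wrist-angle variability heuristic with a
   temperature veto, or externally supplied sleep intervals.
4. **ENMO epoching** — per-day, wear-gated, wake/sleep-split windowed
   Euclidean Norm Minus One.
5. **Endpoints** — time in intensity levels, bouted time, maximum windowed
   acceleration, the intensity gradient, and bout-accumulation
   (fragmentation) metrics.
6. **Statistics** — ICC, repeated-measures correlation, mixed-effects mean
   differences, Cohen's d, per-group age slopes, FDR correction.

A semi-Markov free-living simulator generates recordings with full ground
truth so that every stage can be tested against known answers.

## The acceleration model and ENMO

The accelerometer measures specific force in g: gravity (unit magnitude,
direction set by wrist posture) plus movement acceleration plus sensor
noise, distorted by a per-axis gain and offset. The base intensity metric
is the Euclidean Norm Minus One,

$$\mathrm{ENMO}(t) = \max\!\left(\sqrt{a_x^2 + a_y^2 + a_z^2} - 1,\; 0\right),$$

the residual magnitude after removing gravity, clipped at zero (clipping is
configurable but on by default). ENMO is invariant to wrist orientation,
which is why calibration of the *magnitude* is the step that matters.
Per-sample ENMO is averaged over non-overlapping windows of `wlen` = 5 s
(250 samples at 50 Hz) to form the epoch series from which every endpoint
is computed; a trailing partial window is dropped.

Days are civil local days (midnight to midnight by default; the anchor
hour is configurable, and noon-to-noon windows are used for sleep search).
A day contributes endpoints only when its wear time reaches
`thresh_wear` = 10 h. Non-wear samples are removed before windowing, and
windows never span removed segments — epoching restarts at each contiguous
run, so no epoch mixes non-adjacent data. The wear gate is evaluated per
full day, before the wake/sleep split.

## Calibration

Windows of 10 s whose per-axis standard deviation is below 0.013 g on all
axes are taken as rest; their mean vectors should lie on the unit sphere.
The fit minimises $\sum_i (\lVert s \circ a_i + b \rVert - 1)^2$ over the
gain $s$ and offset $b$ by an iterative projection scheme: calibrated
points are projected radially onto the sphere and each axis regressed onto
its projection (closed-form update), iterated to a maximum parameter
change of $10^{-7}$ (cap 1000 iterations). Identifiability requires sphere
coverage: each axis must contribute rest points of both signs, otherwise
the identity model is returned flagged unconverged, and fits with gains
outside (0.8, 1.2) are rejected. Temperature-dependent gain terms are out
of scope.

On still-orientation simulations (72 orientations, 12 h equivalent,
0.003 g noise) the fit recovers planted gains and offsets to well under
±0.005 (the acceptance suite measures ~5×10⁻⁵). One caveat the simulator
makes visible: if "rest" samples actually carry a small residual
acceleration (e.g. the 0.005 g sleep-level used by the generator), the
gain absorbs it — an inherent property of sphere-based autocalibration,
not an implementation artifact.

## Non-wear detection

The temperature-based detector classifies 1 s windows from three signals:
maximum per-axis acceleration SD, smoothed temperature (1 min moving
median), and temperature slope (centred linear fit over 5 min, °C/min).
Thresholds: SD 0.008 g, low/high temperature 26.0/30.0 °C, decrease rate
−0.2 °C/min, increase rate +0.1 °C/min. A window is non-wear when the
device is cold and still; a sustained decrease leading into such a period
extends the onset backwards to the start of the decrease (this is what
keeps onset error small — skin-warm devices need ~10 min to cool below the
low threshold). Wear is re-asserted on a sustained increase once the
temperature is back above the low threshold, or on high temperature that
is not actively falling. The two hysteresis qualifications matter: a
freshly doffed device still reads above 30 °C while falling, and the
centred slope window "sees" post-rewear warming a couple of minutes early;
without the qualifications both effects mislabel block edges. Ambiguous
windows (moving, mid-range temperature) default to wear, retaining data.
Recording gaps are unioned into non-wear.

The accelerometer-only fallback uses the classic long-window rule: 60 min
windows in 15 min steps, non-wear when at least two axes have SD below
0.013 g and range below 0.050 g; the mask is the union of qualifying
windows (boundary resolution one step), and short wear fragments
(< 30 min) sandwiched between long (≥ 60 min) non-wear are absorbed.

On simulated days with planted doffed blocks the temperature detector
reaches sensitivity and specificity above 0.95 at 1 min resolution (the
acceptance suite measures ≈ 1.00 / 0.9997 over 50 days).

## Sleep windows

The heuristic follows the arm-angle literature: the z-angle
$\arctan(a_z / \sqrt{a_x^2 + a_y^2})$ is computed per 5 s epoch (median
over samples, 5-epoch median smoothing); an epoch is *inactive* when no
successive absolute angle change within the surrounding 5 min reaches 5°
(a "no posture change for five minutes" rule — a rolling *mean* of angle
changes was tried first and discriminates poorly, because median smoothing
shrinks wake-time changes toward the threshold). Within each noon-to-noon
window, inactive blocks of at least 10 min are bridged across gaps shorter
than 60 min and the longest bridged run becomes the candidate; it is kept
if it is at least 30 min long, does not overlap detected non-wear, and its
mean temperature is at least 25 °C (a cold "sleeping" wrist is a doffed
device). One major sleep period per day; naps are out of scope. Boundary
accuracy on simulated nights is well under the 30 min the design aims at,
but the heuristic is a stand-in for full polysomnography-validated
algorithms and is expected to be the weakest link on real data.

## Endpoints

**Cut-points** (half-open, on 5 s epochs directly — no intermediate 1 min
re-averaging): sedentary [0, 0.050) g, light [0.050, 0.110) g, moderate
[0.110, 0.440) g, vigorous [0.440, ∞) g; MVPA ≥ 0.110 g, SLPA < 0.110 g.
Times are epoch counts × 5/60 min, so the four levels always sum to the
period's epoch time.

**Bouted time** uses a tolerance rule: a window qualifies as a bout when
it is at least `bout_min` long, starts and ends in-level, and at least 80%
of its epochs are in-level; reported bouted time is the union of all
qualifying windows. The implementation reduces the fraction condition to a
prefix-sum inequality and finds, for each in-level start, the farthest
admissible end by binary search on a suffix maximum — O(n log n), verified
against an O(n²) enumeration in the tests. Bout lengths default to
{1, 5, 10} min.

**Maximum windowed acceleration** is the maximum epoch-stride rolling mean
over 6 and 15 min windows, missing when the period is shorter than the
window.

**Intensity gradient**: epoch time is histogrammed into 0.025 g bins from
zero; empty bins are dropped (not zero-imputed, since log of zero time is
undefined); the first bin (midpoint 0.0125 g) is included. OLS of ln(time
in bin, minutes) on ln(bin midpoint, g) gives the gradient, intercept and
Pearson r. At least two non-empty bins are required, otherwise the result
is an explicit error and the endpoint is missing (never zero).

## Fragmentation metrics

The wake epoch series is binarised at 0.110 g into SLPA/MVPA (a classic
sedentary-vs-active split at 0.050 g is available behind a flag); maximal
runs are bouts with durations in minutes. Runs abutting a period or
non-wear boundary are censored: they count toward transition probability
and average duration but are excluded, by default, from the
distribution-shape metrics (Gini, hazard, power-law alpha), whose values
they would distort. Metrics are computed per day and averaged across days
per subject; a pooled-bout alternative exists behind a flag.

- transition probability = bouts / total minutes in state = 1 / mean
  duration (exactly, by construction);
- Gini index $\sum_{ij} |d_i - d_j| / (2 n \sum_k d_k)$, computed via the
  sorted-order identity;
- average hazard: mean over distinct durations $t$ of
  $n(t)/n(\ge t)$;
- power-law exponent: continuous MLE
  $\alpha = 1 + n / \sum_i \ln(d_i/d_{\min})$, missing when all durations
  are equal (the estimate diverges).

## Statistical layer

For method comparison: across-day subject means feed the paired t-test,
Pearson correlation and ICC; repeated days feed the repeated-measures
correlation and a random-intercept model on per-day differences. The ICC
defaults to the two-way random-effects absolute-agreement single-measure
form — the usual choice for method comparison, where systematic offsets
should count against agreement — with the F-based 95% CI; the consistency
form is reported alongside because published method comparisons rarely
state which variant they used. The repeated-measures correlation is the
ANCOVA estimator (subject as factor, common slope), with
$N_{obs} - N_{subj} - 1$ degrees of freedom. The mixed model is fitted by
REML via `nlme`; its Wald interval uses *between-subject* degrees of
freedom ($N_{subj} - 1$), since an intercept-only random-intercept model
has effectively one replicate per subject — using the observation-level DF
produces anti-conservative intervals (simulated coverage ~0.92 instead of
~0.97). Singular fits fall back to a one-sample t-test on subject means,
flagged.

For the age analysis: Welch two-group t-tests (no equal-variance
assumption) and |Cohen's d| with pooled n−1-weighted SD on subject means;
separate OLS age slopes per group compared by a Welch-style t on the
combined slope standard errors; Benjamini–Hochberg FDR applied across the
metric family within each analysis table.

## The simulator, and what passing tests do and do not show

`generate_recording()` simulates the measurement chain on a 5 s state
grid: nightly sleep blocks (mean onset 23:00 ± 0.5 h, duration 8 ± 0.5 h,
near-still wrist with posture changes every ~30 min, worn temperature
34 °C), daytime as alternating SLPA/MVPA super-states with exponential
dwell times split into the four levels by sub-state dwells, optional
doffed blocks (exponential duration, mean 90 min, clipped 30–240 min,
frozen acceleration, temperature decaying to 21 °C ambient with a 10 min
time constant), orientation following a random walk on the sphere whose
step size grows with activity state, additive 0.008 g per-axis noise, and
a planted per-axis miscalibration. Dwell times are exponential so that
fragmentation metrics have analytic expectations (transition probability =
1/mean dwell); state mean ENMO levels (0.02/0.075/0.18/0.55 g) straddle
the cut-points.

The defaults describe 7-day, 50 Hz, ±8 g wrist recordings. The younger
preset (SLPA dwell 22 min, MVPA dwell 2.4 min) and older preset (40 min /
1.9 min, slightly lower intensities) were chosen so the pipeline endpoints
land near published healthy-adult group summaries: MVPA time ≈ 100 vs
≈ 40 min/day, SLPA transition probability ≈ 0.05 vs ≈ 0.03 per min, with
the older group's intensity gradient more negative. The tests and the
acceptance script run reduced problem sizes — 1–5 day recordings at 5–10 Hz
and cohorts of 8–10 per group — which keep the whole suite in minutes while
preserving every structural property being tested.

What the simulator does **not** emulate: realistic gait micro-structure
and frequency content (its noise is white; real wrist signals are not),
device-specific noise spectra, temperature dynamics beyond first-order
decay, naps, heavy-tailed dwell-time distributions (available as an
explicit option for power-law tests but not the default), and
subject-level covariance between activity volume and timing. Passing the
closed-loop tests therefore shows the *algorithms* are implemented
correctly and recover planted structure; it does not validate the
thresholds' field accuracy on real populations, which is what the original
device studies are for. The absolute intensity-gradient values produced by
the simulator (≈ −1.3 to −1.6) are shallower than typical free-living
values (≈ −2.3 to −2.6) because the simulator concentrates epoch time at
four discrete levels; the between-group *direction* and effect sizes are
the meaningful quantities.

## Numerical choices and degenerate inputs

- Timestamp steps beyond 1.5 sample intervals split the recording; gaps
  are treated as non-wear. Duplicate or non-monotone timestamps are data
  errors, not warnings.
- Half-open brackets everywhere: a value exactly on a cut-point belongs to
  the level above; interval sets are half-open [start, stop).
- Epoch values exactly on a bin boundary of the intensity-gradient
  histogram go to the upper bin (floor convention).
- Bout-cover comparisons use a 10⁻⁹ slack on the 80% criterion so that
  exact-fraction windows are included regardless of floating-point
  rounding direction.
- Fewer than 9 rest points is an error; 9 or more with bad coverage is an
  unconverged identity model — the caller can always proceed uncalibrated.
- Empty bout lists, degenerate ICC variance, all-equal power-law durations
  and too-short max-window periods all yield missing values (never zero),
  and missing cells are written as empty CSV fields.

## Known limitations

- The sleep heuristic finds one major sleep period per noon-to-noon day
  and will mis-time unusual schedules (shift work, split sleep).
- The temperature-based non-wear detector assumes a worn-to-ambient
  temperature contrast; in hot environments (ambient ≈ skin temperature)
  it degrades toward the accelerometer-only fallback.
- Device binary formats are out of scope; ingestion is CSV only.
- The bout tolerance rule is one of several in circulation; results are
  comparable only across analyses using the same rule and epoch length.
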
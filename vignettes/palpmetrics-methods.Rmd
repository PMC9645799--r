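---
title: "Quantifying vascular palpation skill from simulator sensor streams"
author: "palpmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular palpation skill from simulator sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palpmetrics)
```

## The problem and the data model

Before cannulating an arteriovenous fistula (AVF) for hemodialysis, a
clinician palpates the access to locate the anastomosis by its vibratory
"thrill". `palpmetrics` analyses multimodal recordings of that palpation
phase collected on a bench-top simulator: a flat circular bed carrying
four silicone fistulas, each with a vibration motor at its anastomosis
point. Per trial the simulator logs three fingertip force channels
(thumb, index, middle; N), fingertip and needle-tip positions (mm, in
the bed frame), and a binary flashback line, alongside trial metadata:
which fistula was active, skin thickness, vibration intensity, expert
global-rating-scale (GRS) scores, and the trial outcome `stb` (stable
flashback: at least 2 s of uninterrupted flashback to the end of the
trial).

Subjects are grouped from the two palpation-relevant GRS categories:
high performers (HP) scored 7 in both palpation and overall skill, low
performers (LP) at most 5 in palpation and at most 4 overall, everyone
else is a mid performer (MP). `classify_skill()` implements exactly this
partition of the 7 x 7 score grid.

The sensors run on heterogeneous clocks, so all analysis happens after
`resample_to_grid()` places every channel on one uniform grid (default
100 Hz) spanning the intersection of the channel time ranges. Linear
interpolation bridges gaps up to `gap_max` (default 0.1 s); longer gaps
become missing values rather than invented data, which later drives the
exclusion of trials from location metrics. The binary flashback line is
resampled by previous-value hold. The recording hardware does not
publish its native rates or clock-synchronisation procedure, so the
common grid is this package's reconstruction; the default rate is
configurable everywhere.

## Segmenting the palpation window

Palpation starts when force first appears on the index or middle finger
after a quiet period, and ends when the subject grips the needle —
visible as a thumb-force change coinciding with needle-tip movement.
`detect_palpation_window()` operationalizes this with six thresholds
(`segmentation_config()`), all unavoidable free parameters chosen at the
scale of the sensor noise and exposed in configuration:

* `quiescence_window` (1.0 s) and `start_force_delta` (0.10 N): "no
  change in force" means a peak-to-peak variation below 0.10 N on both
  palpating-finger channels over a trailing 1 s window; the start is the
  first sample rising 0.10 N above the quiescent level. With smoothed
  sensor noise near 0.01 N, 0.10 N is far above chance crossings yet is
  reached within a few tens of milliseconds by ordinary touch pulses.
* `thumb_force_delta` (0.15 N), `needle_disp_threshold` (5 mm) and
  `coincidence_window` (0.5 s): the end requires both a thumb-force
  change and a needle displacement inside the same trailing window.
  Needle jitter at the default position noise stays near 2 mm over
  0.5 s, so 5 mm separates pickup cleanly.
* `smoothing_window` (0.05 s): centred moving average applied to forces
  before thresholding.

Trials with no qualifying start or end return explicit statuses
(`no_start`, `no_end`) and are excluded from metrics. This mirrors how
atypical behaviours must be handled: palpating with the thumb produces
no index/middle rise (`no_start`); carrying the needle in the free hand
throughout leaves no thumb-grip event (`no_end`). A manually annotated
window (from video review) stored in the trial metadata short-circuits
detection and is used as-is.

## Touchpoints and the twelve metrics

A touchpoint is one episode of applied pressure: a local maximum of the
combined index+middle force inside the palpation window with prominence
at least `min_prominence` (0.05 N) and separation at least
`min_separation` (0.10 s; the higher peak wins a conflict, the earlier
on an exact tie). Prior to peak detection the combined force is smoothed
with a triangular-weighted moving average (`smoothing_window`, 0.05 s);
the triangular kernel attenuates sharp apexes less than a flat box, so
half-prominence widths stay within one sample of their closed form on
noiseless signals. The prominence threshold sits at roughly four
standard deviations of the smoothed noise, which keeps spurious peaks
rare without masking light touches.

Per touchpoint:

* `TPT` — dwell time, the full width of the force peak at half
  prominence. The width is measured by counting samples at or above the
  half-prominence level between the first samples falling below
  level − prominence/4 on each side, with sub-sample interpolation at
  the edges. Counting is symmetric under near-level noise, where a
  first-crossing walk is biased inward; the quarter-prominence bound is
  about five noise standard deviations below the level, so noise cannot
  truncate the interval, while neighbouring lower pulses stay outside
  it. A small negative bias (a few percent, largest for the lightest
  touches) remains because sensor noise inflates the measured peak and
  hence the level; this is a property of half-prominence width under
  noise, not of the implementation.
* `TPF` — the combined force at the peak sample.
* `(x, y)` and `TPD` — the planar fingertip position at the peak sample
  and its distance to the active motor. Touchpoints whose position frame
  is missing keep their force fields and drop out of location metrics
  only.

Per trial (labels as conventionally reported):

| metric | definition | units |
|---|---|---|
| Touchpoints | number of detected peaks | count |
| Frequency | Touchpoints / (T_end − T_start) | Hz |
| Total Force | sum of TPT x TPF over touchpoints | N s (reported under the conventional label "Total Force (N)") |
| Force Range | max − min combined force in the window | N |
| Dwell Time | sum of TPT | s |
| Idle Time | window length − Dwell Time | s |
| Path Length | planar length of the (smoothed) fingertip path | mm |
| RCM | % of significant velocity projections toward the motor | % |
| RNTP | % of touchpoints strictly within 40 mm of the motor | % |
| mean TPT / TPF / TPD | per-touchpoint means | s / N / mm |

Two definitional notes. Total Force has units N s (a force-time
integral estimate); the column label "Total Force (N)" follows the
field's reporting convention, and the documentation states the units
prominently. RNTP uses a strict `< 40 mm` comparison, and its
denominator is the number of located touchpoints.

RCM derives from the projected velocity `V_p`: planar fingertip
velocity (central difference on positions smoothed with a 5-sample
moving average) projected on the unit vector from the current position
to the motor, so positive values mean approach. A frame is a
"significant movement" when `|V_p| > 20` mm/s; RCM is the percentage of
significant frames with `V_p > 20` mm/s, undefined when no frame is
significant. Both the 20 mm/s speed threshold and the 40 mm RNTP radius
are fixed constants of the metric definitions.

**Path length and sensor jitter.** Path Length is computed on the same
5-sample-smoothed positions used for velocity, not on raw frames. A raw
path integral at the default position noise (0.5 mm per frame at
100 Hz) accumulates about 0.9 mm of jitter per frame — over a metre per
window, swamping true movement and growing with the sampling rate.
Light smoothing makes the sum a rate-stable estimate of movement;
residual jitter contributes a floor of roughly 0.18 mm per stationary
frame, which the synthetic-data targets account for explicitly.

**Location validity.** Only trials with complete position data during
the window (after bridging sub-0.1 s gaps) enter location-metric group
statistics; force and time metrics tolerate missing positions. This
reproduces the two-tier trial filtering that motivated the design.

## Group comparisons and outcome models

`build_reports()` produces three deterministic tables:

* Pairwise LP–HP, LP–MP and MP–HP comparisons per metric with group
  means *and* medians (reports show both because group-level summaries
  of skewed metrics differ), the Mann–Whitney U statistic, the raw
  two-sided p-value and a star at 0.05/0.01/0.001. No multiple-testing
  correction is applied, matching the raw-p star convention of this
  literature. Comparisons pool trials (ignoring within-subject
  clustering, as the source analyses did); `by_subject = TRUE` switches
  to per-subject medians as a sensitivity analysis.
* Per-group success estimates `k/n` with 95% Wilson score intervals.
  The Wilson interval was chosen for its coverage at moderate `n` and
  its boundary behaviour (never leaving `[0, 1]`).
* Stratified univariate logistic models `logit p(stb) = a + b x` for
  the seven force-model metrics per skill group, fitted by IRLS with a
  Wald test on the slope. Complete separation is detected up front
  (one class entirely above the other on `x`) and flagged instead of
  reporting diverging coefficients.

The Mann–Whitney p-value uses the exact rank distribution when both
samples have at most 8 observations and no ties, and otherwise the
normal approximation with tie and continuity corrections; the exact
branch is validated against exhaustive enumeration of rank arrangements
in the test suite.

Metrics with a significant slope are additionally summarised by a
monotone four-parameter Hill curve
`p(x) = p_min + (p_max − p_min) x^h / (k^h + x^h)` (mirrored when
decreasing), fitted by count-weighted least squares to success rates in
deciles of the metric, under box constraints
`0 <= p_min <= p_max <= 1`, `0.1 <= h <= 10`, `k` within the data
range, from three starts with L-BFGS-B. The decile-binned target and
the functional form are this package's reconstruction of the published
curves, which were shown without formulas. Flat responses are refused
(`fit_failure`) rather than fitted with an unidentifiable `h`.

## The synthetic cohort generator

The study's raw recordings are not deposited, so the package ships a
generator that emulates the *behavioural structure* of the three skill
groups and returns full ground truth for every trial. Each trial is an
explicit event list — quiescence (2–4 s), a train of touch events, a
needle-pickup event, a 3 s tail — rendered to channels at realistic
heterogeneous native rates (forces 80 Hz, positions 100 Hz, flashback
50 Hz) with additive Gaussian sensor noise (defaults 0.02 N force,
0.5 mm position) and zero-clipped force readings, as real force sensors
report.

* **Force pulses** are parabolic arcs whose full width at half maximum
  equals the drawn dwell, so the dwell is recoverable by the
  half-prominence width definition. Dwells and peak forces are
  lognormal (means at the group central values; peak forces truncated
  below 0.08 N, since lighter contacts do not register as distinct
  touches); the first touch is a deliberate firm press (at least
  0.25 N), reflecting how subjects establish initial contact.
* **Touch locations** come from a truncated-lognormal distance-to-motor
  law wrapped in a Gaussian copula: the marginal is solved numerically
  so the group's mean TPD *and* its median per-trial RNTP land on
  target, with a descending drift (homing in over the trial) and AR(1)
  wander; angles follow a random walk. Because per-trial RNTP is
  quantized to multiples of one over the touch count, the generator pins
  the *median of the binomial proportion*, not the per-touch
  probability.
* **Movement between touches** travels during the inter-touch gaps.
  With probability `seek_prob` a move first heads toward the motor (a
  "seek" leg, covering `seek_depth` of the current distance) before
  veering out to the next touch location, and motor-directed travel is
  `toward_slowdown` times slower than outbound travel — deliberate
  haptic homing versus ballistic repositioning. Since RCM is a
  time-frame ratio, these two parameters set RCM; `angle_sd`,
  `wander_rho` and `seek_depth` set path length.
* **Outcome.** `stb` is drawn from a logistic model in the trial's true
  metrics, centred at the group targets, with group intercepts corresponding
  to success probabilities of 0.55 (LP), 0.85 (MP) and 0.95 (HP) at
  exactly-target behaviour (realized cohort averages sit a few points
  lower because the metric spread enters the logistic nonlinearly) and
  slope signs matching the published stratified models (LP success
  falls with idle time, touchpoints and frequency, rises with
  per-touchpoint dwell; MP success falls with dwell time and total
  force, rises with frequency; HP flat). Slope magnitudes are scaled to this
  generator's metric spreads so that the relationships the source found
  significant are detectable at the study's stratum size of roughly 160
  trials.

**Targets are observables, and some are derived.** The published group
central values are mutually inconsistent under any single-trial model:
Dwell Time must equal the sum of per-touchpoint dwells, but the printed
Dwell Time values exceed Touchpoints x TPT by roughly 40%, and the
printed Total Force exceeds Touchpoints x TPT x TPF several-fold. The
generator therefore takes Touchpoints, mean TPT, mean TPF, Idle Time,
mean TPD, RNTP, RCM and Path Length as primary targets at the published
values, and *derives* Dwell Time, Frequency, Total Force and Force
Range from them (e.g. Force Range as the median maximum of the
trial's peak forces plus the apex noise excess). Each profile records
the twelve implied central values in its `targets` element, and the
acceptance checks compare pipeline medians against those.

**Calibration of the movement knobs.** `seek_prob`, `seek_depth`,
`toward_slowdown`, `angle_sd` and `wander_rho` have no closed-form link
to RCM and Path Length, so the defaults were set once by simulating the
full measurement pipeline at the default noise level and matching the
measured group medians to the targets, then frozen. This calibration is
part of the generator's parameterization — measured RCM includes a
dilution from stationary-frame noise and measured Path Length includes
the jitter floor, both of which the calibration absorbs.

**Atypical profiles.** `atypical = "thumb_only"` routes the pulse train
to the thumb channel (no index/middle signal), and
`"needle_in_hand"` removes the pickup event while the needle wanders
throughout; both must be *flagged* by segmentation, not silently
mis-segmented, and the test suite asserts exactly that.

**What the generator does not emulate.** Vibration ("thrill") signal
content, skin/fistula mechanics, needle-insertion dynamics beyond the
pickup event, inter-channel noise correlations, and real dropout
patterns (a single configurable dropout burst per trial stands in for
the latter). Passing the end-to-end checks therefore demonstrates that
the pipeline recovers known behavioural structure from realistic noisy
streams — not that it reproduces the human study's numbers.

## Numerical choices and degenerate inputs

* Resampling onto an identical grid is the identity, making
  `resample_to_grid()` idempotent; channels never extrapolate beyond
  their own valid samples.
* The axis-calibration fit is total least squares via the covariance
  eigendecomposition; clouds with a principal-axis ratio below 1.05 are
  rejected as isotropic, fewer than two distinct points as degenerate.
  The direction sign makes the coordinate with the larger spread
  positive.
* Ties in peak heights break toward the earlier peak; plateaus count
  once at their first sample.
* RCM and RNTP return `NA` (undefined) on empty denominators — a value,
  not an error. Zero-length windows, missing channels, unresampled
  bundles, empty samples, constant outcomes and isotropic clouds raise
  classed conditions (`palpmetrics_*`) that callers can match.
* Random generation is seeded per trial through a counter scheme, so
  any single trial of a cohort can be regenerated in isolation and
  identical seeds give bit-identical artifacts end to end.

## Problem sizes used by the checks

The validation suite exercises: 200 trials for segmentation recovery
(window endpoints within 0.25 s of truth on at least 95%), 100 random
trials for the brute-force metric oracles (agreement to 1e-9),
exhaustive Mann–Whitney enumeration for all sample sizes up to 6 per
group, 100 replicates of n = 500 for logistic Wald coverage against a
dense likelihood-grid oracle, n = 5000 for Hill parameter recovery
(within 15%), and 20 replicate cohorts of 10 subjects x 16 trials per
group for the end-to-end contrasts (group medians within 15% of profile
targets; the eleven expected LP-vs-HP contrasts significant at 0.05;
success ordering LP < MP < HP). These sizes are the package's choice of
a thorough yet routinely runnable validation.

## Known limitations

* Half-prominence dwell estimates carry a small negative noise bias
  (largest for light touches), inherent to the width definition.
* Trial-level pooling ignores within-subject correlation; the
  per-subject mode is a sensitivity check, not a mixed model.
* The Hill fit summarises a relationship; it is not a causal model and
  its `k` is only identified when the decile range brackets it.
* The generator's realism limits are listed above; in particular, no
  claim is made about reproducing the human study's absolute values
  beyond the targeted central values.
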
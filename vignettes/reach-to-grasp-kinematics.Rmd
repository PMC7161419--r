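---
title: "Reach-to-grasp kinematics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reach-to-grasp kinematics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

reachkin analyses three-marker motion-capture recordings of reach-to-grasp
movements — a wrist marker for the transport component and thumb/index
markers for the grip component — performed under different mental-imagery
conditions by practitioners of a mind–body discipline and by untrained
controls. This vignette documents the measurement model, the eleven
kinematic parameters, the motor-flexibility and sustained-attention indices,
the inferential layer, the synthetic-data generator, and the places where
the design was genuinely open.

## Measurement model

Marker positions (mm, 140 Hz) are low-pass filtered coordinate-wise with a
zero-phase (forward–backward) 2nd-order Butterworth filter at 6 Hz — the
standard prehension convention; the dual pass gives an effective 4th-order
magnitude response and no phase distortion. Positions are filtered *before*
differentiation so the derivative does not amplify measurement noise.
Velocity and acceleration use central differences (one-sided at the series
ends). Edge transients are suppressed by symmetric reflection padding, which
preserves constant (resting) segments exactly and, unlike anti-symmetric
reflection, does not amplify noise gradients at the ends.

Derived series per trial: the 3-D resultant wrist speed; its time derivative
(tangential acceleration — the only definition under which a "maximum
deceleration" is meaningful, since the norm of the 3-D acceleration vector
cannot be negative); the thumb–index Euclidean distance (grip aperture); and
the aperture velocity, negative while the hand closes.

## Movement segmentation

* **Onset** — the first sample at which the resultant wrist speed exceeds
  5 mm/s and stays above it for more than 500 ms (the sustain requirement
  makes the rule robust to noise excursions: filtered 0.2–0.3 mm marker
  noise produces speed fluctuations of a few mm/s, but essentially never 70
  consecutive supra-threshold samples).
* **Offset (contact)** — after the maximum grip aperture, the first time the
  grip closing velocity (−aperture velocity), having exceeded 5 mm/s, drops
  back below it. With several closing pulses the first qualifying downward
  crossing is used: contact terminates the movement.

Movement time (MT) is the onset-to-offset interval. Both thresholds and the
sustain window are configurable (`onset.threshold_mm_s`, `onset.sustain_ms`,
`offset.threshold_mm_s`).

## The eleven parameters

Within the movement segment: MT (s); MWV, the peak resultant wrist speed
(m/s); MWDec, the magnitude of the most negative tangential acceleration
*after* the speed peak (m/s², the deceleration phase); MTD, the maximum 3-D
distance of the wrist from the straight line joining the onset and offset
positions (mm), signed by the horizontal component of the deviation along
`cross(movement direction, vertical)` — positive is rightward, and the sign
flips under reflection as it must; MGA, the peak grip aperture (mm); MGCV,
the peak closing velocity after the MGA sample (m/s). The time of each peak
is normalised by MT with onset mapped to 0, giving TMWV, TMWDec, TMTD, TMGA
and TMGCV as proportions. Extrema landing on a segment boundary are flagged
(`flags` column) rather than rejected; a strict mode excludes flagged trials
in the pipeline.

## Range index and d′

Motor flexibility is summarised per participant and parameter by the
**Range**: the difference between the maximum and the minimum of the
participant's per-condition means across the five imagery conditions.
Condition means (not single trials) are the input, matching the magnitudes
such ranges take in practice; the Range is translation-invariant and scales
linearly.

Sustained attention in the letter-detection task is summarised by the
equal-variance signal-detection sensitivity with the loglinear correction:
d′ = Φ⁻¹((hits+0.5)/(n_signal+1)) − Φ⁻¹((false alarms+0.5)/(n_noise+1)),
finite at perfect or zero rates. Because the task is respond-to-every-letter-
except-X, the mapping of button presses to "hits" is ambiguous; both codings
are supported in `cpt_counts()` (default: a hit is a correctly withheld
response on a critical trial).

## Inferential layer

Trial rows are averaged to participant × condition means before modelling,
putting denominator degrees of freedom on the participant scale (e.g. 27 for
the between-group test with 29 participants). Each parameter is fitted with
a REML linear mixed model `value ~ group * condition + (1 | participant)`
with sum-to-zero contrasts; Type-III F tests use Satterthwaite denominator
degrees of freedom. Post hocs are the five within-condition group
differences, Bonferroni-corrected over that family (the smallest family
consistent with how such tables are reported). A planned contrast compares
the most expansive imagery condition (E) with the mean of the other four,
weights (−¼, −¼, −¼, −¼, 1). Singular fits (participant variance estimated
at zero) warn and proceed — the model then *is* its simplified structure.

Range values are regressed on years of practice by ordinary least squares in
the practitioner group only (the predictor is undefined for controls); the
standardized slope of a single-predictor model satisfies β² = R² exactly,
which the tests verify to 1e-10. The d′ group comparison is a two-sided
pooled-variance t-test with Cohen's d computed from the pooled SD.

## Synthetic-data generator

The generator renders full marker recordings whose clean trajectories hit a
requested set of the eleven parameters, so every pipeline stage is testable
without laboratory data.

* **Transport.** The default is a pure minimum-jerk reach: 350 mm (the task
  geometry) in `mt` seconds, bell-shaped speed peaking at `1.875 · D / MT`
  at the midpoint, peak deceleration `5.77 · D / MT²` at normalised time
  `(1 + 1/√3)/2 ≈ 0.789`. Real reaches are asymmetric (speed peaks near 35%
  of MT because MT includes the long low-speed grasp finalisation), so the
  cohort generator uses a target-driven profile instead: a smoothstep rise
  to the requested peak at the requested time, then a deceleration pulse (a
  unit-peak beta-shaped bump with a linear take-off, keeping the speed
  maximum locally quadratic — a flat peak would bias its detected time under
  noise) solved so the deceleration peak value, its timing, and the total
  speed drop are all met.
* **Path.** The wrist follows an arclength-parameterised path: a straight
  reach with an optional lateral bow (an infinitely smooth warped-sine lobe
  in arc fraction, peak placed so the deviation maximum occurs at the
  requested normalised time). Parameterising by arclength makes the designed
  speed profile the exact resultant speed whatever the bow; parameterising
  the bow by arc fraction keeps the lateral motion slow where the wrist is
  slow, so the marker coordinates stay band-limited and the 6 Hz filter does
  not distort them.
* **Aperture.** Opens from 20 mm (digits gently in opposition on the start
  pad) and closes onto the object. The aperture at contact is 95 mm: the
  75 mm cylinder plus a ~20 mm allowance for finger pads and nail-mounted
  markers — with markers on the nails the marker separation at contact
  necessarily exceeds the object diameter, and the study-like cell values
  (MGA ≈ 126 mm with peak closing velocity ≈ 0.11 m/s late in the movement)
  are only jointly realisable under that allowance. The opening (sin²
  velocity lobe) and closing (beta-bump velocity pulse) overlap around the
  aperture maximum so the aperture velocity crosses zero transversally
  there; a flat-topped aperture peak would make the detected TMGA unstable.
  The closing pulse is solved so its peak value, peak time and 5 mm/s
  downward crossing (contact) meet their targets.
* **Noise.** Independent Gaussian noise per axis and sample, SD 0.3 mm on
  the horizontal axes and 0.2 mm on the vertical — the reconstruction
  accuracy of the tracking apparatus.
* **Two truths.** `profile_truth` holds the analytic clean-trajectory
  values. `ground_truth` is the *noise-free pipeline measurement*: the full
  extraction applied to the clean sampled recording. The 6 Hz filter and the
  threshold rules leave small deterministic shifts — most visibly ~30 ms at
  the abrupt contact event, where the closing velocity falls steeply through
  the threshold — that belong to the measurement chain, not to marker noise.
  Recovery bias is therefore assessed against `ground_truth`, isolating what
  noise adds; the deterministic part lives in the difference between the two
  truths.

### Cohorts

`gen_cohort()` draws participant × condition parameter targets around a cell
table of means and SDs (defaults: the study-like values in
`cohort_reference_stats()`: 15 practitioners, 14 controls — one of 30
volunteers excluded — ten trials per condition). The cell SD is split
between a participant random intercept common to all conditions
(`intercept_share`, default 0.5) and a condition-specific deviate;
trial-to-trial scatter adds `trial_sd_frac` (default 0.5) of the cell SD.
The published table gives no within-participant trial SDs, so the 50/50
split is a documented free choice. Years of practice default to the study
composition: one 40-year master, four ~10-year instructors, ten ~6-year
apprentices.

Each trial's targets are *calibrated*: a damped fixed-point loop nudges them
until the noise-free pipeline measurement of the rendered trial matches the
drawn values (the best iterate is kept). Residuals are below ~2% in
amplitude and ~0.04 in normalised time; the hardest case is TMGA at
control-group closing speeds, where the real aperture peak is genuinely
plateau-like and its argmax only weakly determined. Infeasible draws (e.g. a
closing-velocity target inconsistent with the aperture amplitude) are
redrawn around the same cell mean, pulling increasingly toward it, up to 100
attempts.

CPT sessions are equal-variance signal-detection draws: 600 one-second
trials over ten minutes with a 5% critical-stimulus rate (30 signal / 570
noise trials; the rate is a configurable choice, not a published value),
absolute criterion 0.5, with group sensitivity distributions defaulting to
0.98 ± 0.82 (practitioners) and 0.01 ± 1.17 (controls).

## Numerical choices and degenerate inputs

Uniform sampling is enforced at read time to 1e-6 s; missing-sample runs,
single-step jumps over 100 mm, and recordings shorter than 0.7 s (too short
for the 500 ms onset sustain plus margin) are validation issues and the
trial is excluded — no gap interpolation is attempted. Onset scanning is
strict (`>` threshold); offset requires a strict exceedance followed by a
non-strict drop. Coincident start/end positions make the deviation line
undefined (error). Ties in argmax resolve to the earliest sample. All
randomness flows from a single seed with documented per-trial derivations,
so recordings, cohorts and CPT sessions are bit-reproducible.

## Problem sizes used in the validation suite

The shipped checks use: 1,000 random piecewise signals for detector–oracle
equivalence; 500 noise replicates of a control-condition trial for
parameter-recovery bias; 500 null cohorts (29 participants × 5 conditions ×
10 trials at the parameter level) for the type-I-error calibration of the
mixed-model group test; 300 regression cohorts (n = 15) for standardized-
slope recovery; and 1,000 simulated CPT sessions for d′ recovery. Marker-
level test cohorts are kept small (a few participants, one trial per cell)
since per-trial target calibration renders each clean trial several times.

## What passing tests do and do not show

The generator reproduces bell-shaped transport, late asymmetric grasp
closure, plateau-like aperture maxima, band-limited trajectories and
apparatus-level white marker noise. It does not emulate marker occlusion or
mislabelling, soft-tissue artefacts, coloured noise, trial-to-trial
correlations beyond a participant intercept, within-movement corrective
submovements, or any dependence of kinematics on years of practice inside
the cohort generator (the regression helper injects that relationship
directly). Recovery and calibration results therefore validate the pipeline
under clean-lab assumptions; real recordings can violate them, which is why
validation reporting and strict boundary handling are part of the I/O layer.

Known limitations: the detected movement time inherits a ~2-sample
systematic from the onset threshold creep and filter smear at contact
(absorbed into the noise-free measurement definition); the time of peak
closing velocity is the least determined parameter, with noise-induced bias
at the one-sample level; and near-flat closing pulses put the TMGA/TMGCV
argmax at the edge of identifiability — as they would in real data.
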
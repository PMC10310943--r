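---
title: "Methods: gaze event detection, task metrics and the statistical layer"
author: "oculokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze event detection, task metrics and the statistical layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculokit)
```

## Scope

oculokit analyses 60 Hz tablet-based gaze recordings from a three-task
oculomotor battery — fixation (5 trials of 7 s at five locations),
pro-saccades (24 trials: 8 target locations, short 5°/6° and large
10°/12° eccentricities, 3 repeats) and anti-saccades (±10° targets,
100 ms display, 1,200 ms blank, 400 ms arrow, 5 s response screen) —
and turns them into 24 per-subject oculomotor parameters, group
statistics and a diagnostic classifier. The upstream camera-to-gaze
estimation is out of scope: input is already a calibrated 2-D gaze
signal in degrees of visual angle (screen-centre origin, right/up
positive), at a nominal 60 samples/s, with per-sample validity flags.

Because no recordings ship with the package, a ground-truthed simulator
(`synth_gaze()`, `synth_cohort()`) generates every input the test-suite
and the acceptance script use. All reported behaviour of the pipeline is
measured on that simulator; none of it is a claim about any clinical
dataset.

## Event detection at 60 Hz

Saccades are detected with a velocity-threshold (I-VT) detector on
radial speed from central differences (one-sided at the ends of valid
runs). Defaults: onset 30 deg/s, offset 20 deg/s, minimum duration
17 ms with a hard floor of two consecutive supra-threshold samples
(effectively ~33 ms at 60 Hz). Candidate runs are extended outward to
the offset threshold; onset/offset are the first and last samples of
the extended run.

At 60 Hz a saccade of 20–80 ms spans 1–5 samples, which drives several
non-obvious choices:

* **Amplitude from flanking samples.** The displacement is measured
  between the samples just *outside* the event, so the full step is
  captured even when the transit occupies a single inter-sample
  interval. Mean velocity is amplitude over that flanking span (a
  conservative estimate consistent with `peak >= mean`); peak velocity
  is the maximum central-difference speed inside the event and
  systematically underestimates the true peak — at this rate it is a
  lower-bound estimator, which is why the simulator's main-sequence
  parameters are not recovered from it.
* **Median-only filtering in front of the detector.** The general
  denoiser (`denoise()`) is a 5-sample running median followed by
  Savitzky–Golay local quadratic smoothing (window 5). The quadratic
  stage attenuates one-sample transients — exactly what a small saccade
  looks like at 60 Hz — so detection runs on a median-filtered copy
  only (step-preserving), via the internal preprocessing in
  `extract_subject()`.
* **Latency quantisation.** Onsets are quantised to the sample grid;
  central differencing can fire one sample before the physical onset.
  Latency aggregates are therefore accurate to about half a sample
  (±8 ms) plus a small bias well inside the ±5% recovery the tests
  demand. Trials with latency under 80 ms are classed anticipatory and
  excluded from latency/velocity aggregates.

**Saccadic intrusions** (≥0.5°, during fixation) need a separate
operating point: a 0.5–1° square-wave-jerk saccade peaks at ~20–30
deg/s in central differences at 60 Hz, below the main onset threshold.
`detect_intrusions()` therefore uses a lower pair (15/10 deg/s),
accepts single-sample runs (the event physically fits inside one
inter-sample interval), enforces the 0.5° amplitude floor and a 5°
ceiling (larger events inside a fixation window are refixations, not
intrusions), and skips the first 200 ms of the window so the acquiring
saccade is not counted. The thresholds are floors: they rise adaptively
to 5 robust SDs of the in-window velocity noise (estimated from the
75th percentile of radial speed, insensitive to the sparse saccade
samples), so unusually noisy recordings lose sensitivity gracefully
instead of flooding the count with false positives.

Artifacts are masked before any of this: runs of invalid samples and
physiologically impossible speeds (>1,000 deg/s) become intervals
padded by 50 ms and merged; samples inside are flagged invalid, never
altered, and events overlapping an artifact are discarded.

## Task metrics

**Fixation.** Analysis of each trial starts at the later of 200 ms
after target onset and the first sample within 3° of the target —
before gaze has acquired the new target the samples measure the
previous fixation, not this one. Dispersion (68%/95% bivariate contour
ellipse area and horizontal/vertical gaze SD) is computed on the
*unsmoothed* artifact-masked samples, re-centred on the target, with
whole intrusion episodes excised: for a square-wave jerk the eye sits
displaced between the outward and return saccades, so the exclusion
spans from the first onset to the second offset. BCEA uses
`2*pi*k*sd_H*sd_V*sqrt(1-rho^2)` with `k = -ln(1-P)`; the 95/68 area
ratio is the constant `ln(0.05)/ln(0.32) ≈ 2.629`. The intrusion rate
divides counted intrusions by analysed (valid, post-acquisition)
fixation time; by default a paired outward/return couple within 250 ms
counts as one intrusion, so the rate is in square-wave-jerk pairs per
second — set `swj_pair_window_s = 0` in `detection_config()` for
per-saccade counting.

**Pro-saccades.** The first saccade is the earliest event after target
onset with amplitude ≥1° and displacement toward the target. First
gain is its along-axis displacement over the target eccentricity
(robust to orthogonal error); first gain error is the full 2-D landing
error. Arrival is the first dwell of ≥100 ms inside a 2° acceptance
window (values typical for 10° targets; the protocol does not fix
them); saccades-to-target counts detected saccades up to arrival.
Per-trial metrics are averaged separately over short and large
eccentricity classes; non-responsive trials are tallied, not averaged.

**Anti-saccades.** The first saccade after target onset is correct if
its horizontal component points away from the target side; an error
trial is corrected if a later saccade lands on the opposite side of
centre before arrow offset. Latency on error trials is the latency of
the error saccade itself. Arrow recognition is scored from the 5 s
response screen: per-direction dwell of gaze more than 2° off-centre
(left/right when |x| ≥ |y|, up/down otherwise); the longest dwell is
the answer only if it reaches 0.5 s — a deliberate response on a 5 s
screen — otherwise the trial counts as unrecognised. One reading of
"mean velocity" is the per-trial average over all saccades; here it is
the first saccade's mean velocity, consistent with the other
first-saccade metrics.

## The simulator and what it does (not) emulate

`synth_gaze()` builds an event timeline per trial and renders it at
60 Hz: raised-cosine saccade profiles whose peak velocity follows the
main sequence `Vmax*(1-exp(-A/C))` (defaults Vmax = 500 deg/s, C = 5°,
healthy-adult literature values), truncated-normal latencies with an
80 ms floor, primary gain with optional corrective saccades closing
the residual, Poisson square-wave-jerk intrusions (two opposite
saccades 200 ms apart, at least 0.55 s between pairs), white tracker
noise plus slow random-walk drift, and blinks as invalid runs. The
truth log records every injected event exactly.

Key calibration choices, made once:

* **Noise floor.** The white (sample-to-sample) noise SD defaults to
  0.15° (0.17° for the patient profile). A tracker validated to resolve
  0.5° intrusions cannot have much more frame-to-frame jitter than
  this at 60 Hz — 0.25° white noise would imply 0.35° RMS
  sample-to-sample jumps and make the instrument's own intrusion
  definition meaningless. Slower error components are carried by the
  drift term (which scales with the noise SD and vanishes in the
  noiseless limit). The tablet's true noise spectrum is not public, so
  the simulator exposes both knobs.
* **Intrusion amplitudes** are truncated at 0.55°: the modelled process
  is the population of ≥0.5° intrusions that the assessment defines,
  not sub-threshold microsaccades.
* **Cohort spread.** Between-subject square-wave-jerk rates are
  lognormal (sdlog 0.85, capped at 0.8 pairs/s — pairs need ~0.5 s of
  refixation, so higher nominal rates cannot be realised). Published
  rates in older adults span roughly 2–50 per minute, and this spread
  is also what makes the per-subject rate identifiable from ~32 s of
  analysed fixation, where pure Poisson counting noise is ~30%.
* **Group effects** follow the directions and rough magnitudes
  reported for Parkinson's disease in tablet-based assessment: intrusion
  pair rate ×1.887, primary gain −13%, more corrective (multi-step)
  saccades, slightly shorter latency, higher short-eccentricity mean
  velocity, more anti-saccade errors. A latent severity score
  (UPDRS-III-like, mean 27.6, SD 13.8) couples negatively to gain and
  positively to the log intrusion rate.

What the simulator does **not** emulate: pixel-space camera noise and
head motion, pursuit, vergence, pupil dynamics, non-stationary
attention, asymmetric or oblique square-wave jerks, express saccades,
and any correlation structure between tasks beyond the shared profile.
Passing recovery tests therefore demonstrates that the pipeline
measures what the generator injected under plausible signal
characteristics — not that it reproduces clinical values, which would
require the original recordings.

## Statistical layer

Demographics use Welch's t from summary statistics and Pearson's
chi-square without continuity correction. Severity correlations are
gated by Shapiro–Wilk on *both* variables at α = 0.05 (pair-wise
gating; single-variable gating is a config away in
`correlate_with_severity()`): Pearson if both pass, Spearman with
average ranks otherwise. Group comparisons fit
`response ~ group + age + sex` (sex as a binary indicator,
complete-case): the family-level MANCOVA reports Pillai's trace — the
robust default among the multivariate statistics — with the standard F
approximation from type-III cross-product matrices, and per-parameter
post-hoc ANCOVAs report the partial (type-III) F for group, computed
by model comparison so it stays defined even for degenerate
zero-residual inputs, plus covariate-adjusted means and percent
difference. Benjamini–Hochberg correction is applied separately within
each task family (fixation, pro-saccade, anti-saccade), matching the
per-table presentation of the parameters.

## Classifier evaluation

The diagnostic model is logistic regression with an L2 penalty on the
mean negative log-likelihood (`lambda * ||w||^2 / 2`, intercept
unpenalised, default λ = 1 on standardised features), fitted by damped
Newton iterations to gradient norm 1e-8. The six default features are
the fixation intrusion rate; short-eccentricity first gain, mean
velocity, mean latency and saccades-to-target; and the
large-eccentricity first gain error. Evaluation uses 1,000 stratified
70/30 random subsamples: standardisation is fitted on each training
fold only (the no-leakage test adds a pure-noise feature and checks
AUC moves < 0.02), the mean ROC is a vertical average over a fixed FPR
grid, AUC/sensitivity/specificity CIs are 2.5/97.5 percentiles over
subsamples, and the point sensitivity/specificity come from pooled
test confusion counts at probability 0.5. On the default synthetic
cohort (50 per group) the declared mean-AUC band is 0.70–0.95,
asserted in the tests. The band is deliberately a property of the
simulator defaults, not a reproduction target: the synthetic cohort
mirrors the *directions* of the published group effects, and its
separability is moderate — in particular, short-eccentricity
saccades-to-target carries little signal here because a typical
hypometric undershoot on a 5° target still lands inside the 2°
acceptance window, whereas in clinical recordings that parameter is
among the strongest discriminators.

## Problem sizes and numerical conventions

The test-suite and acceptance script use: 10,000-point Monte-Carlo
BCEA coverage; 100 single-saccade traces (2–12°, noise SD 0.2°) for
detection recall/precision/amplitude bias; a 50-per-group cohort
(three tasks each, ~230 s of gaze per subject) for end-to-end
parameter recovery; 1,000 null simulations for ANCOVA type-I
calibration; 1,000 fuzz cases for the AUC pair-counting identity; and
200–1,000 subsamples for classifier reports. Ties in ranks use
averages; all randomness flows from explicit seeds; reading rejects
rather than coerces (missing columns and non-monotone time are
errors, invalid samples are flagged and carried).

## Known limitations

Peak velocity (and to a lesser degree mean velocity) is biased low at
60 Hz and should be read comparatively, not absolutely. Saccade onsets
are sample-quantised. Intrusion detection below ~0.7° degrades
gracefully as recording noise grows (the adaptive threshold trades
sensitivity for specificity). The anti-saccade arrow-recognition score
is a gaze-dwell proxy for a perceptual report. The MANCOVA's "F(df)"
bookkeeping follows the Pillai F approximation (`df1 = s(2m+s+1)`,
`df2 = s(2n+s+1)`); with a single response it reduces exactly to the
univariate ANCOVA F, which the tests assert to 1e-9.
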
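# oculokit

Analysis toolkit for tablet-based oculomotor assessment: from raw 60 Hz
2-D gaze recordings of a three-task battery (fixation, pro-saccades,
anti-saccades) to per-subject oculomotor parameters, group statistics
and a diagnostic classifier — plus a ground-truthed gaze simulator so
the whole pipeline is testable without any recordings.

It is aimed at researchers working on digital oculomotor biomarkers
(e.g., for Parkinson's disease), where consumer-grade 60 Hz eye
tracking makes event detection and parameter estimation harder than on
research-grade infrared systems.

## What it computes

From each subject's recordings, 24 canonical parameters:

* **Fixation (5):** 68% and 95% bivariate contour ellipse area,
  horizontal/vertical gaze SD, and the rate of saccadic intrusions
  (≥ 0.5°). BCEA is `2πk·σ_H·σ_V·√(1−ρ²)` with `k = −ln(1−P)`.
* **Pro-saccades (7 × short/large eccentricity):** latency,
  time-to-target, mean and peak saccade velocity, first-saccade gain
  (amplitude / target eccentricity), first gain error (2-D landing
  error), and the number of saccades needed to reach the target
  (multi-step saccades).
* **Anti-saccades (5):** direction error rate, corrected rate, arrow
  recognition rate, correct- and incorrect-direction latency.

Saccades are found with a velocity-threshold (I-VT) detector (onset
30 deg/s, offset 20 deg/s), with a dedicated low-amplitude operating
point for saccadic intrusions; blinks and impossible-velocity spikes
are masked first. The statistical layer provides Welch's t and
chi-square for demographics, Shapiro–Wilk-gated Pearson/Spearman
severity correlations, MANCOVA (Pillai's trace) with post-hoc
type-III ANCOVAs adjusted for age and sex, and Benjamini–Hochberg FDR
correction per task family. The classifier is ridge-regularised
logistic regression on six parameters, evaluated over 1,000 stratified
random train/test subsamples (mean ROC, AUC and
sensitivity/specificity with percentile CIs, pooled confusion matrix).

See `vignettes/oculokit-methods.Rmd` for the models, assumptions,
calibration choices and limitations.

## Worked example

Simulate one parkinsonian subject's pro-saccade run, extract their
parameters, and test a demographics difference:

```r
library(oculokit)

sched <- make_schedule("prosaccade", seed = 42)   # 24 trials
prof  <- default_profile("PD")
sim   <- synth_gaze(sched, prof, seed = 42, subject_id = "PD001")
sim$recording
#> <gaze_recording> subject PD001, task prosaccade: 5616 samples @ 60 Hz (93.6 s, 99.1% valid)

res <- extract_subject(list(prosaccade = sim$recording),
                       list(prosaccade = sched),
                       demographics = list(group = "PD", age = 64,
                                           sex = "M", updrs3 = 30))
row <- res$parameters
sprintf("short latency %.0f ms, first gain %.2f", 1000 * row$pro_short_latency,
        row$pro_short_first_gain)
#> "short latency 212 ms, first gain 0.81"
sprintf("large first gain %.2f, gain error %.2f deg",
        row$pro_large_first_gain, row$pro_large_first_gain_error)
#> "large first gain 0.80, gain error 2.19 deg"

welch_t(63.76, 8.23, 59, 56.64, 8.56, 62)$t   # age difference, two groups
#> 4.661731
```

The short-eccentricity latency (212 ms) and first gain (0.81) recover
the generating profile (mean latency 200 ms, gain 0.83) to within
trial-sampling noise; the gain error is the mean 2-D distance between
the first saccade's landing point and the target.

A whole two-group cohort, end to end:

```r
cohort <- synth_cohort(cohort_config(n_per_group = 10, seed = 7))
params <- extract_cohort(cohort)                  # 20 x 24 parameter table
stats  <- analyze_parameter_table(params)         # correlations + ANCOVAs
report <- subsample_evaluate(params, seed = 7)    # ridge-logistic ROC report
```

Or from the shell, with everything written to disk
(`parameters.csv`, QC sidecar, stats tables, classifier report,
checksummed manifest):

```sh
Rscript inst/exec/oculokit run --config inst/extdata/example_run.yaml
```

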
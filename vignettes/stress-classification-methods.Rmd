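---
title: "Methods: window features, stress labeling and ensemble classification for wrist-worn sensor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window features, stress labeling and ensemble classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`stresswear`, the assumptions behind them, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## The measurement model

Acute stress engages the sympathetic nervous system: sweat-gland activity
raises skin conductance (electrodermal activity, EDA), cardiac drive
raises heart rate (HR), and peripheral vasoconstriction lowers skin
temperature (TEMP). A wrist wearable samples these at different native
rates (EDA/TEMP at 4 Hz, HR as a derived 1 Hz stream), and an observer
annotates perceived stress continuously on [0, 1]. The analysis assumes
the annotation is time-aligned with the physiology and that class-relevant
information lives at the 10-second window scale.

## Preprocessing

All channels are brought to a unified 4 Hz grid. Interpolation is linear;
the slower HR stream is upsampled rather than downsampling EDA/TEMP, so no
high-rate information is discarded. The grid is anchored at the latest
channel start and spans the intersection of the channel spans, including
both endpoints (`floor(span · 4) + 1` points) — a deterministic, testable
boundary rule. Grid points falling inside runs of missing input stay
missing through resampling and are then imputed with the per-channel,
per-session median. The median is computed over the whole session rather
than per window: a window-local median would distort windows that are
mostly missing, and session-level missingness in this setting is small
(about 1 %). Resampling before imputation means missing runs propagate to
the grid and are filled exactly once.

## Window features

Windows are 40 samples (10 s) with a step of 20 (50 % overlap). Per
window, 19 features:

* min, max, mean and standard deviation of each channel (12). The
  standard deviation uses the population denominator *n*, matching moment
  estimators used for the shape statistics.
* EDA sample skewness (Fisher–Pearson, `m3/m2^1.5`) and excess kurtosis
  (`m4/m2^2 − 3`), both defined as 0 for zero-variance windows so constant
  windows produce finite rows.
* the SCR peak triple: peaks are strict local maxima with topographic
  prominence at least `peak_prominence` (default 0.01 µS, a conventional
  SCR detection threshold; fully configurable). Amplitude is the summed
  prominence; duration is the summed peak width measured at
  `peak_width_fraction` (default 0.5) of the prominence below the peak,
  linearly interpolated between samples and converted to seconds at 4 Hz.
  Plateau samples are not counted as peaks; this is deliberate — a flat
  maximum in 4 Hz EDA is almost always quantization, and the strict rule
  keeps the detector deterministic.
* RMS of first differences of HR and TEMP, a short-term variability
  measure.

The means of EDA/HR/TEMP from each of the previous 1–10 windows are
appended (`3 × max_lag` columns, 30 at the default). The lag-k feature is
the value of the single window k steps back, not an average over the last
k windows. The first `max_lag` windows of each subject are dropped rather
than zero-padded: padding would fabricate history and bias early-session
windows toward whatever filler value was chosen. Lags never cross subject
boundaries.

One published description of this feature set counts 18 current-window
features (48 with lags); the enumerated list above sums to 19 (49). The
package implements the enumerated list and reports counts from the
configuration rather than hard-coding either number.

Features are min-max scaled to [0, 1]. Scalers are fit on training folds
only and applied to validation/test folds — pooled scaling leaks the
held-out range into training. Zero-range columns map to 0 everywhere so a
constant column cannot produce NaNs.

## Labeling

A window's label is the mean of the continuous stress annotation over the
window span `[t, t + 10 s)`, thresholded at θ₁ and θ₂ with left-closed
intervals (a mean exactly at θ₁ is class 1), giving classes 0/1/2 = no /
medium / high stress. The thresholds used by the original annotation
protocol are not recoverable; the defaults are the tertile cut points 1/3
and 2/3 of the annotation scale and are configurable. Labeling is
per-window (the unit the classifiers see); session-level labeling can be
recovered by aggregating the per-window means.

## Model selection and evaluation

The protocol is: one stratified 80/20 split; nested cross-validation on
the 80 % for hyperparameter selection; a final refit on the (scaled) 80 %
and a single evaluation on the 20 %. Nested CV uses stratified 5-fold at
both levels: the inner level scores each candidate configuration by mean
fold accuracy on the outer-training part (scalers fit inside every inner
training split), the winner is refit on the outer-training part and
scored on the outer-test part. Accuracy is the selection criterion
throughout. The per-fold class counts deviate from proportional
allocation by at most one.

Base-learner search spaces follow the randomized-search convention:
100 candidate draws (integer ranges uniform inclusive; the gradient-
boosting learning rate uniform on [0.01, 0.31]). The random forest space
covers `n_estimators` 50–300, depth 10–30, `sqrt`/`log2` feature
subsampling, split/leaf minima and bootstrap on/off; gradient boosting
covers `n_estimators` 50–300 and depth 3–10. The comparison learners use
exhaustive grids sized 45 (logistic regression), 24 (SVM), 16 (KNN) and
125 (AdaBoost), giving 225/120/80/625 fits under 5-fold CV. The logistic
grid is C {0.001, 0.01, 0.1, 1, 10} × elastic-net mixing α {0, 0.5, 1} ×
iteration cap {100, 500, 1000}: the mixing parameter replaces a solver
choice that has no analogue among R optimizers while preserving the grid
size, and the iteration cap is advisory — when no penalty point converges
within it, the optimizer widens its warm-start path and finishes, so every
grid candidate yields a usable model.

Implementation notes. The random forest is a Gini-split probability
forest; bootstrap off means the full sample is used per tree. Gradient
boosting starts from the class-prior log-odds (supplied as the base
margin), which makes it a stagewise additive model in the classical
sense: a learning rate of 0 degrades exactly to the majority class.
AdaBoost is the multiclass SAMME algorithm over depth-limited CART trees;
a stage with zero weighted error is taken with full weight and the
sequence stops, and a stage no better than chance stops the sequence.
KNN supports Manhattan and Euclidean metrics with uniform or
inverse-distance weights; an exact-match neighbour (distance 0) dominates
the vote.

The stacking classifier trains both base ensembles, collects their
out-of-fold class probabilities from an internal stratified 5-fold pass
(2 models × 3 classes = 6 meta-features), and fits a multinomial logistic
meta-learner on those probabilities. Prediction applies the meta-learner
to the refit base models' probabilities. Out-of-fold features are
essential: in-sample base probabilities would hand the meta-learner
overfit inputs.

Reports follow the standard classification-report layout: per-class
precision/recall/F1/support with the 0-when-undefined convention,
accuracy, macro (unweighted) and weighted (support-weighted) averages
over the three classes. With a fixed master seed every stage — fold
assignment, candidate draws, tree fitting — is bit-reproducible; every
derived seed stays below 2³¹.

## Interpretation

Feature importance is mean decrease in impurity:
`I(f) = (1/T) Σ_t Σ_{n ∈ N_{f,t}} Δi(n)`, where `Δi(n)` is the
node-weighted Gini decrease of split node *n*, afterwards normalized so
the importances sum to one. For the forest this is recomputed from first
principles — the training samples are routed through every fitted tree
with their bootstrap multiplicities and the per-node decreases
accumulated — rather than read off a summary attribute; the test suite
verifies the recomputation against the fitting library's own impurity
importance to 10⁻⁹. For gradient boosting the recorded per-split gain of
the booster plays the role of the impurity decrease in the same equation.

Group statistics compare the per-window channel means across stress
levels (1 vs 0 and 2 vs 0). A literally paired test is not defined across
unequal-sized window groups, so the default is Welch's unequal-variance
two-sample t-test in the level-minus-baseline direction; a subject-paired
variant on per-subject level means is available when subjects experience
both levels. Significance is flagged at α = 0.001. Time-in-level
summaries report each subject's class fractions and flag subjects whose
class-2 fraction strictly exceeds 0.25; segment validation marks a
subject as passing when at least half of its emergency-segment windows
are labeled 1 or 2 — the published account states the outcome (all
subjects elevated during the emergency) but not the rule, so the majority
rule here is this package's choice, with the threshold configurable.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the study's scale: 12 subjects × 7200 s (86,400 s total), six scenario
segments per session with segment 4 forced to high stress, EDA/TEMP at
4 Hz and HR at 1 Hz, and 1.02 % of samples missing completely at random.
The stress profile is piecewise constant at the label-band centers (1/6,
1/2, 5/6) with smooth AR(1) jitter (SD 0.04), clipped to [0, 1]. Channel
levels are piecewise-linear in the stress value through per-level targets
taken from observed group means — HR 82.23/86.30/84.79 bpm, TEMP
31.81/31.49/31.23 °C, EDA 0.68/2.09/1.87 µS. The HR target for level 2
deliberately sits below level 1, following the observed values rather
than a monotone idealization; monotonicity holds for levels 0→1 for HR
and 0→1→2 for TEMP and EDA.

Around those levels the signal models are the package's own choices, made
once: HR noise is AR(1) (marginal SD 2 bpm, coefficient 0.95); TEMP adds
a slow AR(1) drift (SD 0.08 °C) and measurement noise (SD 0.05 °C); EDA
is a tonic level plus phasic SCRs — Poisson arrivals at 1/4/8 per minute
at the three band centers, gamma-distributed amplitudes with mean 0.3 µS,
convolved with a bi-exponential kernel (rise 0.75 s, decay 2 s) — plus
smooth low-amplitude noise, floored at 0. The EDA noise SD (0.003 µS) is
kept below the SCR prominence threshold so the peak detector is not
swamped by measurement noise, as it would not be on hardware-filtered
EDA. Phasic activity adds positive skew, so empirical EDA means run
above the tonic targets by up to ~15 % at level 0; HR and TEMP
calibration errors stay well under 1 %.

What the generator does **not** emulate: motion artifacts and sensor
detachment, circadian and thermoregulatory drift, inter-subject
variability in baseline physiology, annotation lag between observed
behaviour and the slider, and autocorrelated missingness. Consequently,
passing tests demonstrate that the pipeline recovers the structure it
assumes — monotone stress effects, calibrated levels, separable classes —
not that comparable accuracy would be reached on field recordings, where
class overlap is larger and artifacts matter.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full-scale generator
(17k windows) for calibration and group statistics, and run model
selection on a stratified 1200-row subsample with 20 randomized draws per
search — sizes chosen so a complete nested 5×5 search for both base
ensembles finishes in minutes on one CPU while leaving every fold
comfortably stratifiable. Grid-search bookkeeping is exercised on a
2-subject, 100-row reduction with current-window features only.

Other conventions: timestamps are epoch seconds with no time-zone
handling; trace values outside [0, 1] are rejected, never clipped;
channel files must carry a numeric start time and positive rate; the
feature-table reader rejects non-canonical column names and headerless
files; windows without any trace points raise coverage errors naming the
window; classes with fewer members than folds raise stratification
errors. Known limitations: the SCR detector does not deconvolve
overlapping responses (closely spaced SCRs merge into one peak), lag
features assume uninterrupted sessions, and the label thresholds — while
configurable — default to tertiles of the annotation scale rather than
values learned from data.
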
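---
title: "Methods: response and gaze analysis of Go/NoGo sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response and gaze analysis of Go/NoGo sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazenogo)
```

## The measurement setting

A child sits in front of a monitor with a screen-mounted eye tracker and
plays a Go/NoGo game: a stimulus appears for 700 ms at one of nine fixed
screen positions, the child presses the spacebar for Go stimuli and withholds
for NoGo stimuli, and a new stimulus follows after a 700-1000 ms waiting
period. The system logs four variables: the response type of every trial, the
response time, and the stimulus and gaze positions over time, with all
coordinates normalized to the unit square. Each trial is one of four types —
Go-positive (pressed on Go), Go-negative (missed a Go), NoGo-positive
(correctly withheld), NoGo-negative (failed to withhold) — and the response
time is the latency from stimulus onset to the first press attributed to the
trial's window.

The package turns such session logs into per-subject feature vectors, group
statistics and a classification benchmark. Because no recorded cohort ships
with it, a seeded simulator generates cohorts with the same timing protocol
and plausible clinical contrasts, so every stage is testable end to end.

## Preprocessing

Cleaning happens in a fixed order:

1. **Response-time outliers.** Presses faster than a threshold are treated as
   anticipatory and their trials are dropped from the RT statistics. The
   threshold is the median absolute deviation of the response times scaled by
   1.4826 (the normal-consistency constant); the comparison is strict (`<`),
   so ties at the threshold survive. By default the MAD is computed over all
   subjects' RTs pooled — a single cohort-level threshold — with a
   per-subject option in `preprocess_config()`. Whether an outlier trial's
   *gaze* should also be discarded is genuinely ambiguous; the default keeps
   the gaze for spatial features and only removes the trial from RT
   statistics (`drop_gaze_for_outliers` exposes the alternative).
2. **Downsampling.** Plain decimation by 2 (144 Hz to 72 Hz). No anti-alias
   filter: at the native rate consecutive samples are largely duplicated
   (interlaced logging) and smoothing follows anyway.
3. **Savitzky-Golay smoothing.** Window 5, degree 2, applied to the x and y
   coordinates to prevent artifacts in numerical differentiation. The same
   filter provides the first and second derivatives for the kinematic
   features, scaled to per-second units.

## The 24 spatial features

`extract_spatial_features()` emits, per subject: the four response-type
percentages, the RT mean and SD (Go and NoGo pooled); the convex-hull area
of the gaze trajectory; the mean and SD of gaze speed and acceleration
magnitude (Savitzky-Golay derivatives); the mean and SD of fixation dwell —
time inside a circle of radius 0.25 around the stimulus center during its
appearance; the mean and SD of the step distance \(d(t) = |g(t+1) - g(t)|\)
and of the angle between consecutive *position vectors*
\(\arccos\big(g(t+1)\cdot g(t) / (|g(t+1)||g(t)|)\big)\); sample entropies of
the step-distance, angle and speed series; the normalized Shannon entropy of
the gaze occupancy histogram (100 × 100 cells over the unit square); and
three entropies of the gaze-to-stimulus difference (gaze minus stimulus
center while the stimulus is on screen): a kernel-density entropy (Gaussian
product kernel, Scott's-rule bandwidth, 50 × 50 evaluation lattice), the
sample entropy of the Euclidean gaze-object distance, and a spectral entropy
(Welch PSD, segment length 32, Hann window, 50% overlap; x and y spectra
summed per bin). Throughout, "avg" is the arithmetic mean and "var" the
sample standard deviation.

Conventions worth stating exactly:

* **Sample entropy** uses template length `m = 2`, Chebyshev distance with
  tolerance `r = 0.2 × SD` of the series (the tolerance is unstated in the
  protocol; 0.2 SD is the field convention and is exposed in
  `entropy_config()`), templates taken at all `n - m` offsets so every
  counted length-`m` pair can extend, and self-matches excluded. A constant
  series gives 0; a series with no matching pairs gives `NA`.
* **Histogram and KDE entropies** are normalized by `log2` of the total cell
  count, so they live in [0, 1]. The angle uses absolute position vectors as
  the protocol defines it (not displacement vectors); zero-magnitude
  positions contribute angle 0.
* **Spectral entropy** shrinks its segment to the series length (with a
  message) when a difference series is shorter than 32 samples, and returns
  `NA` below 4 samples.
* **Fixation dwell** sums all in-circle intervals of a trial by default;
  `fixation_mode = "first_interval"` restricts to first-entry-to-first-exit.
  Both readings of "time between entering and leaving" are defensible.
* Degenerate sessions propagate `NA` features with a message; imputation
  happens only inside classification training folds.

## Gaze-adjustment dynamics

For each trial the gaze-to-stimulus distance series (normalized units, hence
in \([0, \sqrt 2]\)) from onset to the response (or offset) is fitted with a
second-order autoregression

\[ y_t = \alpha + \theta_1 y_{t-1} + \theta_2 y_{t-2} + \varepsilon_t \]

by ordinary least squares. Segments shorter than 8 samples (3 parameters
plus headroom) are flagged unfittable and excluded from averages; constant
segments produce a rank-deficient design resolved by pseudo-inverse and
flagged. The per-fit AIC uses the Gaussian profile form
`n_eff log(RSS/n_eff) + 2k` with `k = 3`; its absolute scale depends on that
convention, so only comparisons between fits of the same kind are
meaningful.

Coefficients are averaged arithmetically per group, either pooled ("mixed")
or per response type, and the average dynamics are extrapolated from
`y_1 = y_2 = init` over a horizon of 50 steps (about 700 ms at 72 Hz). The
*gaze-adjustment velocity* is the mean of the negative first difference of
the extrapolated series — positive when the gaze approaches the stimulus —
reported per step and per second. Initial condition and horizon are not
pinned down by the protocol; the defaults take `init` as the cohort mean of
segment starting distances (fallback 0.5) and both are configurable, since
the velocities depend on them.

## Statistics

`compare_two_groups()` runs, per feature, a pooled-variance Student *t* test
(Welch optional), a Mann-Whitney *U* test (two-sided normal approximation
with tie correction), and Cohen's *d* with the typical group first — so a
negative *d* means the clinical group's mean is larger. The
Benjamini-Hochberg step-up procedure controls the FDR at `q = 0.05` across
the features tested in one run (the implicit family); a feature is flagged
significant when both the *t* and *U* families survive. Three-group
comparisons use one-way fixed-effects ANOVA. For the gaze-adjustment
coefficients, subject-by-response-type cell means are treated as
observations (a 52-subject cohort contributes up to 208 cells in mixed
mode); this mirrors the protocol's accounting but overstates the effective
sample size, and is said so in the function documentation.

## Classification protocol

Raw per-trial coefficients are summarized per subject into four moments
(skewness, excess kurtosis, mean, SD — scipy-convention type-1 moments) per
cell and coefficient: 12 values in mixed mode, 48 in by-response-type mode.
Cells with one fit take shape moments 0 by convention; cells a subject lacks
entirely are `NA` and are imputed with training-fold means. The moment block
is z-normalized and reduced to 5 components with neighborhood component
analysis (PCA-initialised, BFGS-optimised, deterministic for fixed inputs);
"significant" spatial features (the fixed eight: velocity-sen,
acceleration-avg, fixation-var, distance-sen, angle-sen, gaze-obj-en,
gaze-obj-sen, gaze-obj-spe — or the current run's BH-significant set, per
config) and optionally the six game-performance features are appended after
reduction, giving 13 or 19 columns.

The classifier is AdaBoost (SAMME) over depth- and leaf-limited `rpart`
trees, each tree seeing a random half of the features; hyperparameters are
grid-searched (depth {1,3,5,7}, leaves {3,5,7}, rounds {15,25,50,75},
learning rate {0.5,0.75}) by inner stratified 3-fold accuracy, with the
boosting rounds evaluated as staged prefixes of one ensemble. Evaluation is
*nested* stratified 3-fold cross-validation: imputation, z-normalization,
NCA and the grid search are all fitted inside each outer training fold —
the protocol description leaves the nesting open, and non-nested evaluation
inflates small-sample scores, so nesting is the default with a
`nested = FALSE` compatibility flag. The held-out folds are scored with
accuracy, MCC (generalized multi-class form, which reduces to the binary
formula) and AUC from class probabilities (macro one-vs-rest for three
classes); a probability threshold of 0.5 converts the clinical-class
probability to a label in the two-class task. Confusion matrices are pooled
over folds and row-normalized to percentages.

## The synthetic cohort generator

The generator reproduces the game's timing exactly (700 ms appearances,
uniform 700-1000 ms waits, nine grid locations, balanced preset Go/NoGo
order) and models a subject as a noisy proportional pursuit with per-trial
attention lapses:

* On an **attended** trial the gaze, after a subject-specific latency, moves
  a fraction `gaze_gain` of the remaining distance to the stimulus per
  sample, plus isotropic Gaussian noise; between stimuli it drifts toward
  screen center with the same gain (the protocol does not describe
  inter-trial gaze; center drift is an assumption, flagged here). Go trials
  are pressed with `p_go_respond` at a lognormal latency truncated to the
  trial window; NoGo presses occur with `1 - p_nogo_inhibit`. With
  probability `p_anticipatory` (default 0.05) a press becomes premature
  (< 120 ms), so the MAD filter has something to remove.
* On a **lapsed** trial (probability `p_lapse`) the pursuit gain is
  multiplied by `lapse_gain_factor` (0.25) and a Go press occurs only with
  probability 0.1. Lapses are the load-bearing design choice: they couple
  response types to gaze dynamics — misses mostly carry weak-approach
  segments, correct responses engaged ones — which is precisely the
  structure that makes separating gaze-adjustment features by response type
  informative. A generator whose trials all share one gain was tried first
  and contradicts the analysis's premises: its pooled coefficients separate
  the groups trivially and response-type separation can only add noise.

The default group presets are config values, not measurements: typical
subjects use gain 0.32, latency 120 ms, noise SD 0.01, lapse rate 0.10;
the ASD presets use gain 0.27, latency 150-160 ms, noise SD 0.02-0.022,
lapse rates 0.30/0.34, lower Go accuracy and inhibition, and a larger RT
log-SD (0.40-0.45 vs 0.25). The contrasts are chosen so that the clinical
group shows higher gaze-signal entropies, shorter and more variable
stimulus dwell, and modest pooled but clear type-specific differences in
approach dynamics — the qualitative directions the analysis is designed to
detect. Between-subject jitter (lognormal, SD 0.08) individualizes profiles
within groups, and one master seed reproduces a cohort exactly.

What the generator does **not** emulate: blinks, tracker dropout, head
movement, saccadic (as opposed to smooth) gaze shifts, learning or fatigue
across the session, and the heavier-tailed noise of real eye trackers.
Passing tests therefore show the pipeline recovers structure *of this kind*
faithfully; they do not certify performance on recorded cohorts — on the
synthetic defaults the classifier saturates near 100% accuracy, which real
data should not be expected to match.

## Numerical choices and degenerate inputs

* Gaze coordinates are clipped to the unit square; strict I/O validation
  rejects out-of-range values, lax validation clips with a message.
* The SG filter uses the full-matrix endpoint treatment, so outputs keep the
  input length; tests assert interior values.
* NCA stabilizes its softmax by subtracting the row-minimum squared
  distance; its reduction errors out when the requested dimension exceeds
  the rank of the (centered) training block — with 3-fold CV this needs
  roughly `n_components + folds/2 + 1` subjects per training fold, which the
  52-subject design comfortably satisfies.
* AdaBoost stops early on a perfect round (which then dominates the vote) or
  when a round's weighted error reaches the random-guess bound; a
  single-class training fold yields a constant classifier.
* Zero-magnitude position vectors, empty response sets, segments too short
  to fit, spectrally empty signals and point-mass difference distributions
  all degrade to documented conventions (0 or `NA`) with messages rather
  than errors.

## Problem sizes used by the test suite

The suite exercises the full protocol at sizes chosen to keep a complete
run inside a normal development cycle: unit tests use seconds-long sessions
and cohorts of up to a dozen subjects; the structural replication test runs
twenty 20-subject cohorts with one-minute sessions for the
feature-significance check and three full-composition cohorts (31/11/10,
four-minute sessions) for the classification-modality ordering. The
acceptance script runs the complete default pipeline — 52 subjects,
four-minute sessions, full hyperparameter grid — in a few minutes on one
CPU.

## Known limitations

* The simulator's contrasts are cleaner than clinical reality; synthetic
  classification scores are ceiling-level and should be read as a pipeline
  check, not an expected clinical effect size.
* Treating subject-by-type cells as independent observations in the
  coefficient statistics ignores within-subject correlation.
* The AR(2) extrapolation velocity depends on the (configurable) initial
  condition and horizon; comparisons are meaningful only within one
  configuration.
* Fixation detection is a single dwell circle; no saccade/fixation event
  segmentation is attempted.
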
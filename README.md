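# gazenogo

Response and gaze behavior analysis for Go/NoGo eye-tracking sessions.

Inhibitory-control games of the Go/NoGo family — press for the Go
character, withhold for the NoGo character, while a screen-mounted eye
tracker records where the child looks — yield two intertwined behavioral
signals: *what* the child answered (response types and latencies) and *how*
their gaze tracked the stimulus. Differences in the spatio-temporal
structure of that gaze signal, rather than in global summaries, are what
separate autistic from typically developing children in this paradigm.
`gazenogo` is for researchers who want a tested, reproducible implementation
of that analysis: it validates and round-trips session logs, simulates
seeded cohorts for development and benchmarking, and carries a session from
raw log to classification report.

## What it computes

* **Preprocessing** — anticipatory-response removal at the scaled-MAD
  threshold `1.4826 × MAD(RT)`, decimation from 144 to 72 Hz, and
  Savitzky-Golay smoothing (window 5, degree 2).
* **24 spatial features** per subject: response-type percentages, RT mean
  and SD, convex-hull trajectory area, SG-derivative speed and acceleration
  statistics, fixation dwell (radius-0.25 circle) statistics, step distance
  `d(t) = |g(t+1) − g(t)|` and position-vector angle statistics, sample
  entropies (m = 2, Chebyshev, r = 0.2 SD) of distance, angle, speed and
  gaze-to-stimulus distance, a 100×100 occupancy entropy, and KDE (50×50)
  and Welch spectral (nperseg = 32) entropies of the gaze-to-stimulus
  difference.
* **Gaze-adjustment dynamics** — per-trial AR(2) fits
  `y_t = α + θ₁y_{t−1} + θ₂y_{t−2}` of the gaze-to-stimulus distance,
  arithmetic group averages (pooled or per response type), and forward
  extrapolation whose mean negative first difference is the
  *gaze-adjustment velocity*.
* **Statistics** — pooled-variance Student *t*, Mann-Whitney *U*, Cohen's
  *d* (typical group first), one-way ANOVA for three groups, and
  Benjamini-Hochberg FDR control at q = 0.05.
* **Classification** — moment summaries (skewness, kurtosis, mean, SD) of
  the AR coefficients per response-type cell, NCA reduction to 5
  components, z-normalization, and grid-searched AdaBoost over decision
  trees, evaluated with leakage-free nested stratified 3-fold CV
  (accuracy, MCC, AUC, pooled row-percent confusion matrices).

## A worked example

```r
library(gazenogo)

cfg <- schedule_config(duration = 60000)          # one-minute session
sch <- generate_stimulus_schedule(cfg, seed = 42)
s   <- simulate_session(group_presets()$typical, sch, cfg, seed = 42)
s
#> <session_log> subject sim (typical)
#>   8640 gaze samples @ 144 Hz over 60.0 s, 38 stimuli (19 go), 17 presses

pre   <- preprocess_session(s)
feats <- extract_spatial_features(pre$session, pre$trials)
feats[, c("go_pos_pct", "rt_mean", "fixation_avg",
          "distance_sen", "gaze_obj_sen", "gaze_obj_spe")]
#> # A tibble: 1 × 6
#>   go_pos_pct rt_mean fixation_avg distance_sen gaze_obj_sen gaze_obj_spe
#>        <dbl>   <dbl>        <dbl>        <dbl>        <dbl>        <dbl>
#> 1       78.9    438.         596.        0.895       0.0710        0.553
```

This subject answered 78.9% of Go trials, with a mean latency of 438 ms,
and dwelt on the stimulus for 596 ms of each 700 ms appearance on average.
The low sample entropy of the gaze-to-stimulus distance (0.071) says the
approach is highly predictable — the signature of engaged tracking; ASD
presets produce visibly higher values.

Fitting and extrapolating the gaze-adjustment dynamics:

```r
fits <- fit_adjustments(segment_adjustments(pre$session, pre$trials))
avg  <- average_coefficients(dplyr::mutate(fits, group = "typical"), "mixed")
avg
#> # A tibble: 1 × 6
#>   group     alpha theta1 theta2   aic n_fits
#>   <chr>     <dbl>  <dbl>  <dbl> <dbl>  <int>
#> 1 typical 0.00381   1.46 -0.625 -334.     38

extrapolate_ar(avg, init = 0.45, horizon = 50)
#> <ar_extrapolation> 50 steps, velocity 0.0087 per step (0.6279 per s)
```

The positive velocity (0.0087 normalized units per step) quantifies how
fast the average fitted dynamics close the gaze-to-stimulus distance.

For a whole cohort, `run_pipeline(pipeline_config(seed = 1))` simulates 52
subjects (31 typical, 11 ASD without ADHD, 10 with), extracts features,
runs the statistical battery and the classification protocol, and returns
one reproducible bundle; `autoplot()` methods display sessions,
extrapolations and classification reports, and `tidy()`/`glance()` give
per-fold and one-row summaries of fitted objects.

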
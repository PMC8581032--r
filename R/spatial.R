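# The 24 spatial attributes summarizing one subject's response and gaze
# behavior: game performance (response percentages and RT statistics),
# absolute gaze position (trajectory area, kinematics, step distance/angle,
# spatial entropy) and gaze-to-stimulus movement (fixation dwell and the
# entropy family of the gaze-object difference). "avg" is the arithmetic
# mean and "var" the sample standard deviation throughout.

#' Names of the 24 spatial features
#'
#' @return Character vector of the 24 attribute names, in canonical order.
#' @export
spatial_feature_names <- function() {
  c("go_pos_pct", "go_neg_pct", "nogo_pos_pct", "nogo_neg_pct",
    "rt_mean", "rt_var",
    "trajectory_area", "velocity_avg", "velocity_var",
    "acceleration_avg", "acceleration_var",
    "fixation_avg", "fixation_var",
    "distance_avg", "distance_var", "angle_avg", "angle_var",
    "distance_sen", "angle_sen", "velocity_sen",
    "spatial_en", "gaze_obj_en", "gaze_obj_sen", "gaze_obj_spe")
}

#' Gaze trajectory area
#'
#' Area of the convex hull of the gaze points; with coordinates normalized
#' to the unit square the area is already a fraction of the screen in
#' `[0, 1]`. Fewer than three distinct non-collinear points give area 0.
#'
#' @param gaze Gaze tibble (`x`, `y`) or any data frame with those columns.
#' @return Hull area in `[0, 1]`.
#' @export
trajectory_area <- function(gaze) {
  pts <- unique(cbind(gaze$x, gaze$y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(0)
  x <- pts[h, 1]
  y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Gaze speed and acceleration magnitude series
#'
#' Savitzky-Golay smoothed first and second time-derivatives of the x and y
#' coordinates, combined as Euclidean magnitudes:
#' speed `v = sqrt(x'(t)^2 + y'(t)^2)` (normalized units per second) and
#' acceleration `a = sqrt(x''(t)^2 + y''(t)^2)` (units per second squared).
#'
#' @param gaze Uniformly sampled gaze tibble (`x`, `y`).
#' @param sample_rate_hz Sampling rate of `gaze`.
#' @param window,poly Savitzky-Golay parameters (defaults 5 and 2).
#' @return Tibble with columns `v` and `a`, same length as the input.
#' @export
kinematics <- function(gaze, sample_rate_hz, window = 5, poly = 2) {
  dt <- 1 / sample_rate_hz
  dx1 <- smooth_sg(gaze$x, window, poly, deriv = 1, dt = dt)
  dy1 <- smooth_sg(gaze$y, window, poly, deriv = 1, dt = dt)
  dx2 <- smooth_sg(gaze$x, window, poly, deriv = 2, dt = dt)
  dy2 <- smooth_sg(gaze$y, window, poly, deriv = 2, dt = dt)
  tibble::tibble(v = sqrt(dx1^2 + dy1^2), a = sqrt(dx2^2 + dy2^2))
}

#' Step distance and angle between consecutive gaze positions
#'
#' Distance is the Euclidean step length `|g(t+1) - g(t)|`. The angle is
#' taken between the absolute position vectors `g(t)` and `g(t+1)`
#' (arc-cosine of their normalized dot product, clamped into `[-1, 1]`); a
#' zero-magnitude position vector yields angle 0 for that step.
#'
#' @param gaze Gaze tibble (`x`, `y`) with at least 2 rows.
#' @return Tibble with columns `distance` and `angle` (radians), one row per
#'   consecutive pair.
#' @export
step_distance_angle <- function(gaze) {
  n <- nrow(gaze)
  if (n < 2) abort("need at least 2 gaze samples")
  x0 <- gaze$x[-n]; y0 <- gaze$y[-n]
  x1 <- gaze$x[-1]; y1 <- gaze$y[-1]
  distance <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n0 <- sqrt(x0^2 + y0^2)
  n1 <- sqrt(x1^2 + y1^2)
  zero <- n0 == 0 | n1 == 0
  if (any(zero)) {
    inform(sprintf("%d zero-magnitude position vector(s); angle set to 0",
                   sum(zero)))
  }
  cosang <- rep(1, n - 1)
  cosang[!zero] <- pmin(pmax(
    (x0[!zero] * x1[!zero] + y0[!zero] * y1[!zero]) /
      (n0[!zero] * n1[!zero]), -1), 1)
  tibble::tibble(distance = distance, angle = acos(cosang))
}

#' Gaze-to-stimulus difference series
#'
#' Per-sample gaze position minus stimulus center while the stimulus is on
#' screen (half-open windows `[onset, offset)`), concatenated over trials in
#' presentation order.
#'
#' @param session A (preferably preprocessed) [session_log()].
#' @return Tibble with columns `trial_id`, `t`, `dx`, `dy`; zero rows when no
#'   gaze sample falls in any appearance window.
#' @export
gaze_object_difference <- function(session) {
  st <- session$stimuli
  g <- session$gaze
  if (nrow(st) == 0) {
    return(tibble::tibble(trial_id = integer(), t = numeric(),
                          dx = numeric(), dy = numeric()))
  }
  purrr::map(seq_len(nrow(st)), function(i) {
    idx <- which(g$t >= st$onset[i] & g$t < st$offset[i])
    tibble::tibble(trial_id = st$trial_id[i], t = g$t[idx],
                   dx = g$x[idx] - st$cx[i], dy = g$y[idx] - st$cy[i])
  }) %>% bind_rows()
}

#' Fixation dwell times
#'
#' Time the gaze spends inside the stimulus area — a circle of Euclidean
#' radius `radius` around the stimulus center — during each appearance
#' window. `mode = "total"` (default) sums all in-circle intervals of a
#' trial; `mode = "first_interval"` counts only from first entry to first
#' exit. Trials whose gaze never enters the circle contribute 0.
#'
#' @param session A preprocessed [session_log()].
#' @param radius Fixation-area radius in normalized units (default 0.25).
#' @param mode `"total"` or `"first_interval"`.
#' @return One-row tibble `fixation_avg`, `fixation_var` (ms; mean and
#'   sample SD over trials), with the per-trial dwell table attached as
#'   attribute `"dwell"`.
#' @export
fixation_times <- function(session, radius = 0.25,
                           mode = c("total", "first_interval")) {
  mode <- match.arg(mode)
  st <- session$stimuli
  g <- session$gaze
  dt_ms <- 1000 / session$sample_rate_hz
  dwell <- vapply(seq_len(nrow(st)), function(i) {
    idx <- which(g$t >= st$onset[i] & g$t < st$offset[i])
    if (length(idx) == 0) return(0)
    inside <- sqrt((g$x[idx] - st$cx[i])^2 + (g$y[idx] - st$cy[i])^2) <= radius
    if (!any(inside)) return(0)
    k <- if (mode == "total") {
      sum(inside)
    } else {
      runs <- rle(inside)
      runs$lengths[which(runs$values)[1]]
    }
    k * dt_ms
  }, numeric(1))
  out <- tibble::tibble(
    fixation_avg = if (length(dwell) == 0) NA_real_ else mean(dwell),
    fixation_var = if (length(dwell) < 2) 0 else sd(dwell)
  )
  attr(out, "dwell") <- tibble::tibble(trial_id = st$trial_id,
                                       dwell_ms = dwell)
  out
}

#' Extract the 24 spatial features of one session
#'
#' Assembles the full spatial feature vector from a preprocessed session and
#' its (outlier-filtered) classified trials. Individually undefined features
#' (e.g. entropies of a degenerate series) propagate as `NA` with a message;
#' they are imputed only at the classification stage.
#'
#' @param session A preprocessed [session_log()] (see
#'   [preprocess_session()]).
#' @param trials Outlier-filtered classified trials; recomputed (without
#'   outlier removal) when `NULL`.
#' @param entropy An [entropy_config()].
#' @param sg_window,sg_poly Savitzky-Golay parameters for the kinematics.
#' @param fixation_radius Fixation-area radius (default 0.25).
#' @param fixation_mode Dwell mode, see [fixation_times()].
#' @return One-row tibble: `subject_id`, `group`, then the 24 features in
#'   [spatial_feature_names()] order.
#' @export
extract_spatial_features <- function(session, trials = NULL,
                                     entropy = entropy_config(),
                                     sg_window = 5, sg_poly = 2,
                                     fixation_radius = 0.25,
                                     fixation_mode = "total") {
  trials <- trials %||% classify_responses(session)
  g <- session$gaze

  resp <- response_stats(trials)
  fix <- fixation_times(session, fixation_radius, fixation_mode)

  sen <- function(x) {
    if (length(x) <= entropy$m + 1 || sd(x) == 0) {
      if (length(x) > entropy$m + 1 && sd(x) == 0) return(0)
      inform("series too short for sample entropy; feature missing")
      return(NA_real_)
    }
    sample_entropy(x, m = entropy$m, r_factor = entropy$r_factor)
  }

  if (nrow(g) >= sg_window) {
    kin <- kinematics(g, session$sample_rate_hz, sg_window, sg_poly)
  } else {
    inform("gaze track shorter than the smoothing window; kinematics missing")
    kin <- tibble::tibble(v = NA_real_, a = NA_real_)
  }
  sda <- if (nrow(g) >= 2) step_distance_angle(g) else {
    tibble::tibble(distance = NA_real_, angle = NA_real_)
  }
  god <- gaze_object_difference(session)
  obj_dist <- sqrt(god$dx^2 + god$dy^2)

  vec <- tibble::tibble(
    subject_id = session$subject_id,
    group = session$group,
    go_pos_pct = resp$go_pos_pct, go_neg_pct = resp$go_neg_pct,
    nogo_pos_pct = resp$nogo_pos_pct, nogo_neg_pct = resp$nogo_neg_pct,
    rt_mean = resp$rt_mean, rt_var = resp$rt_var,
    trajectory_area = trajectory_area(g),
    velocity_avg = mean(kin$v), velocity_var = sd_or_zero(kin$v),
    acceleration_avg = mean(kin$a), acceleration_var = sd_or_zero(kin$a),
    fixation_avg = fix$fixation_avg, fixation_var = fix$fixation_var,
    distance_avg = mean(sda$distance), distance_var = sd_or_zero(sda$distance),
    angle_avg = mean(sda$angle), angle_var = sd_or_zero(sda$angle),
    distance_sen = sen(sda$distance), angle_sen = sen(sda$angle),
    velocity_sen = sen(kin$v),
    spatial_en = histogram_entropy_2d(g$x, g$y, entropy$spatial_bins,
                                      range_x = c(0, 1), range_y = c(0, 1)),
    gaze_obj_en = if (nrow(god) >= 2) {
      kde_entropy(god$dx, god$dy, entropy$kde_grid)
    } else NA_real_,
    gaze_obj_sen = sen(obj_dist),
    gaze_obj_spe = if (nrow(god) >= 4) {
      spectral_entropy(god$dx, god$dy, entropy$nperseg)
    } else NA_real_
  )
  vec
}

sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) == 1) return(0)
  sd(x)
}

#' Extract spatial features for a whole cohort
#'
#' Preprocesses the sessions with a pooled outlier threshold (see
#' [preprocess_cohort()]) and extracts the 24 spatial features per subject.
#'
#' @param sessions List of [session_log()] objects.
#' @param config A [preprocess_config()].
#' @param entropy An [entropy_config()].
#' @param ... Passed on to [extract_spatial_features()].
#' @return Tibble with one row per subject (`subject_id`, `group`, 24
#'   features), with the preprocessing report attached as attribute
#'   `"preprocess_report"`.
#' @export
extract_cohort_features <- function(sessions, config = preprocess_config(),
                                    entropy = entropy_config(), ...) {
  pre <- preprocess_cohort(sessions, config)
  out <- purrr::map2(pre$sessions, pre$trials, function(s, tr) {
    extract_spatial_features(s, trials = tr, entropy = entropy,
                             sg_window = config$sg_window,
                             sg_poly = config$sg_poly, ...)
  }) %>% bind_rows()
  attr(out, "preprocess_report") <- pre$report
  attr(out, "threshold_ms") <- pre$threshold_ms
  out
}
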
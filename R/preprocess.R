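# Session cleaning, in the fixed order: response-time outlier removal, then
# downsampling, then Savitzky-Golay smoothing.

#' Preprocessing configuration
#'
#' @param mad_scale Scale factor turning a median absolute deviation into a
#'   normal-SD equivalent (default 1.4826).
#' @param downsample_factor Keep every k-th gaze sample (default 2, i.e.
#'   144 Hz to 72 Hz).
#' @param sg_window Savitzky-Golay window length in samples (odd, default 5).
#' @param sg_poly Savitzky-Golay polynomial degree (default 2).
#' @param pooled_threshold Compute the RT outlier threshold from all
#'   subjects' RTs pooled (`TRUE`, the default) or per subject.
#' @param drop_gaze_for_outliers Also drop an outlier trial's gaze segment
#'   from spatial features (default `FALSE`: the trial leaves the RT
#'   statistics only).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(mad_scale = 1.4826, downsample_factor = 2,
                              sg_window = 5, sg_poly = 2,
                              pooled_threshold = TRUE,
                              drop_gaze_for_outliers = FALSE) {
  if (downsample_factor < 1) abort("`downsample_factor` must be >= 1")
  if (sg_window %% 2 != 1 || sg_window <= sg_poly) {
    abort("`sg_window` must be odd and greater than `sg_poly`")
  }
  structure(
    list(mad_scale = mad_scale, downsample_factor = downsample_factor,
         sg_window = sg_window, sg_poly = sg_poly,
         pooled_threshold = pooled_threshold,
         drop_gaze_for_outliers = drop_gaze_for_outliers),
    class = "preprocess_config"
  )
}

#' MAD-based response-time outlier threshold
#'
#' The threshold below which a response time is considered anticipatory:
#' the unscaled median absolute deviation of the response times multiplied by
#' `mad_scale`. With a MAD of 104.75 ms and the default scale this is
#' 1.4826 x 104.75 = 155.30 ms.
#'
#' @param rts Response times, ms (at least one).
#' @param mad_scale Scale constant (default 1.4826).
#' @return Threshold in ms.
#' @export
#' @examples
#' mad_rt_threshold(c(200, 300, 400, 500, 600))  # MAD 100 -> 148.26
mad_rt_threshold <- function(rts, mad_scale = 1.4826) {
  rts <- rts[!is.na(rts)]
  if (length(rts) == 0) abort("need at least one response time")
  mad_scale * median(abs(rts - median(rts)))
}

#' Remove response-time outliers
#'
#' Drops classified trials whose response time is strictly below the
#' threshold (ties are kept); trials without a press are never dropped.
#'
#' @param trials Output of [classify_responses()].
#' @param threshold Threshold in ms (>= 0), e.g. from [mad_rt_threshold()].
#' @return List with `trials` (kept rows) and `report`, a one-row tibble with
#'   `threshold_ms`, `n_responses`, `n_removed` and `fraction_removed`.
#' @export
remove_rt_outliers <- function(trials, threshold) {
  if (threshold < 0) abort("`threshold` must be >= 0")
  is_outlier <- !is.na(trials$rt) & trials$rt < threshold
  n_resp <- sum(!is.na(trials$rt))
  list(
    trials = trials[!is_outlier, , drop = FALSE],
    report = tibble::tibble(
      threshold_ms = threshold,
      n_responses = n_resp,
      n_removed = sum(is_outlier),
      fraction_removed = if (n_resp == 0) 0 else sum(is_outlier) / n_resp
    )
  )
}

#' Downsample a gaze track
#'
#' Plain decimation: keeps every `factor`-th sample starting from the first.
#' No anti-alias filter is applied; at the native rate consecutive samples
#' are largely duplicated (interlaced logging) and smoothing follows anyway.
#'
#' @param gaze Gaze tibble (`t`, `x`, `y`).
#' @param factor Integer >= 1.
#' @return The decimated gaze tibble.
#' @export
downsample_gaze <- function(gaze, factor) {
  if (factor < 1) abort("`factor` must be >= 1")
  gaze[seq(1, nrow(gaze), by = factor), , drop = FALSE]
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Least-squares local polynomial filtering of a uniformly sampled series;
#' derivative orders 1 and 2 return time-derivatives in units per second
#' (and per second squared). Output has the same length as the input, with
#' the edge samples fitted on shrinking one-sided windows.
#'
#' @param series Numeric vector, length >= `window`.
#' @param window Odd window length (default 5).
#' @param poly Polynomial degree (default 2).
#' @param deriv Derivative order 0, 1 or 2.
#' @param dt Sampling interval in seconds (default 1).
#' @return Numeric vector of the same length.
#' @export
smooth_sg <- function(series, window = 5, poly = 2, deriv = 0, dt = 1) {
  if (length(series) < window) {
    abort(sprintf("series length %d is shorter than the window (%d)",
                  length(series), window))
  }
  signal::sgolayfilt(series, p = poly, n = window, m = deriv, ts = dt)
}

#' Preprocess one session
#'
#' Applies the fixed cleaning order to a session: RT outlier removal on its
#' classified trials, gaze decimation, then Savitzky-Golay smoothing of the
#' x and y coordinates (smoothed positions are clipped back into the unit
#' square).
#'
#' @param session A [session_log()].
#' @param trials Classified trials; computed with [classify_responses()] when
#'   `NULL`.
#' @param threshold RT outlier threshold in ms; when `NULL` it is computed
#'   from this session's own RTs with [mad_rt_threshold()]. Pass a pooled
#'   cohort threshold for the cohort-level protocol (see
#'   [preprocess_cohort()]).
#' @param config A [preprocess_config()].
#' @return List with `session` (cleaned log), `trials` (outlier-filtered
#'   classified trials) and `report` (one-row tibble: threshold, removal
#'   counts, rates before/after in Hz).
#' @export
preprocess_session <- function(session, trials = NULL, threshold = NULL,
                               config = preprocess_config()) {
  trials <- trials %||% classify_responses(session)
  if (is.null(threshold)) {
    rts <- trials$rt[!is.na(trials$rt)]
    threshold <- if (length(rts) == 0) 0 else
      mad_rt_threshold(rts, config$mad_scale)
  }
  filtered <- remove_rt_outliers(trials, threshold)

  gaze <- downsample_gaze(session$gaze, config$downsample_factor)
  if (nrow(gaze) >= config$sg_window) {
    gaze$x <- pmin(pmax(smooth_sg(gaze$x, config$sg_window, config$sg_poly), 0), 1)
    gaze$y <- pmin(pmax(smooth_sg(gaze$y, config$sg_window, config$sg_poly), 0), 1)
  }
  out <- session
  out$gaze <- gaze
  out$sample_rate_hz <- session$sample_rate_hz / config$downsample_factor
  report <- filtered$report
  report$rate_before_hz <- session$sample_rate_hz
  report$rate_after_hz <- out$sample_rate_hz
  list(session = out, trials = filtered$trials, report = report)
}

#' Preprocess a cohort with a pooled outlier threshold
#'
#' The outlier threshold is computed once from all subjects' response times
#' pooled (a single cohort-level threshold), then every session is cleaned
#' with [preprocess_session()]. Set `pooled_threshold = FALSE` in the config
#' for per-subject thresholds.
#'
#' @param sessions List of [session_log()] objects.
#' @param config A [preprocess_config()].
#' @return List with `sessions` (cleaned), `trials` (list of filtered trial
#'   tables), `threshold_ms`, and `report` (per-subject removal rows).
#' @export
preprocess_cohort <- function(sessions, config = preprocess_config()) {
  all_trials <- purrr::map(sessions, classify_responses)
  pooled_rts <- unlist(purrr::map(all_trials, ~ .x$rt[!is.na(.x$rt)]))
  threshold <- if (config$pooled_threshold && length(pooled_rts) > 0) {
    mad_rt_threshold(pooled_rts, config$mad_scale)
  } else {
    NULL
  }
  pre <- purrr::map2(sessions, all_trials, function(s, tr) {
    preprocess_session(s, trials = tr, threshold = threshold, config = config)
  })
  report <- purrr::imap(pre, function(p, i) {
    mutate(p$report, subject_id = sessions[[i]]$subject_id, .before = 1)
  }) %>% bind_rows()
  list(
    sessions = purrr::map(pre, "session"),
    trials = purrr::map(pre, "trials"),
    threshold_ms = threshold %||% NA_real_,
    report = report
  )
}
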
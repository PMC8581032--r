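# Gaze-adjustment dynamics: per-trial gaze-to-stimulus distance series,
# AR(2) fits y_t = alpha + theta1 y_{t-1} + theta2 y_{t-2}, group averages
# of the coefficients, and forward extrapolation of the average dynamics to
# a gaze-adjustment velocity.

MIN_AR_SEGMENT <- 8L  # 3 parameters plus headroom

#' Segment per-trial gaze-adjustment series
#'
#' For each trial, the Euclidean gaze-to-stimulus distance per gaze sample
#' from stimulus onset up to the response (if any) or the stimulus offset,
#' labelled with the trial's response type. With normalized coordinates the
#' distance lies in `[0, sqrt(2)]`. Segments shorter than the minimum
#' fittable length (8 samples) are emitted but flagged unfittable.
#'
#' @param session A preprocessed [session_log()].
#' @param trials Classified trials (see [classify_responses()]); recomputed
#'   when `NULL`.
#' @return Tibble with one row per trial: `trial_id`, `response_type`,
#'   `series` (list column of distance vectors), `dt` (sample interval, s),
#'   `n`, `fittable`.
#' @export
segment_adjustments <- function(session, trials = NULL) {
  trials <- trials %||% classify_responses(session)
  g <- session$gaze
  dt <- 1 / session$sample_rate_hz
  series <- purrr::map(seq_len(nrow(trials)), function(i) {
    end <- if (!is.na(trials$rt[i])) {
      min(trials$onset[i] + trials$rt[i], trials$offset[i])
    } else {
      trials$offset[i]
    }
    idx <- which(g$t >= trials$onset[i] & g$t < end)
    sqrt((g$x[idx] - trials$cx[i])^2 + (g$y[idx] - trials$cy[i])^2)
  })
  tibble::tibble(
    trial_id = trials$trial_id,
    response_type = trials$response_type,
    series = series,
    dt = dt,
    n = lengths(series),
    fittable = lengths(series) >= MIN_AR_SEGMENT
  )
}

#' Fit an AR(2) model to a distance series
#'
#' Ordinary least squares of `y_t` on `(1, y_{t-1}, ..., y_{t-L})`. The AIC
#' uses the Gaussian profile likelihood, `n_eff * log(RSS / n_eff) + 2 k`
#' with `k = L + 1` parameters and `n_eff = n - L` fitted points. A
#' rank-deficient design (e.g. a constant series) is resolved by the
#' pseudo-inverse and flagged `degenerate`.
#'
#' @param series Numeric vector, length >= `max(lag + 3, 8)`.
#' @param lag Model order (default 2).
#' @return An `ar_fit` object: coefficients `alpha`, `theta` (length `lag`),
#'   `aic`, `n`, `degenerate`. [tidy()] and [glance()] methods are provided.
#' @export
fit_ar <- function(series, lag = 2) {
  n <- length(series)
  if (n < max(lag + 3, MIN_AR_SEGMENT)) {
    abort(sprintf("series of length %d is too short for an AR(%d) fit", n, lag))
  }
  y <- series[(lag + 1):n]
  X <- cbind(1, vapply(seq_len(lag), function(i) {
    series[(lag + 1 - i):(n - i)]
  }, numeric(n - lag)))
  qrx <- qr(X)
  degenerate <- qrx$rank < ncol(X)
  if (degenerate) {
    coefs <- as.numeric(MASS::ginv(X) %*% y)
    inform("rank-deficient AR design (constant series?); pseudo-inverse fit")
  } else {
    coefs <- qr.coef(qrx, y)
  }
  resid <- y - as.numeric(X %*% coefs)
  n_eff <- length(y)
  rss <- sum(resid^2)
  aic <- if (rss <= 0) -Inf else n_eff * log(rss / n_eff) + 2 * (lag + 1)
  structure(
    list(alpha = unname(coefs[1]), theta = unname(coefs[-1]),
         aic = aic, n = n, degenerate = degenerate),
    class = "ar_fit"
  )
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("<ar_fit> alpha = %.4f, theta = (%s), aic = %.3f, n = %d\n",
              x$alpha, paste(sprintf("%.4f", x$theta), collapse = ", "),
              x$aic, x$n))
  invisible(x)
}

#' @export
tidy.ar_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", paste0("theta", seq_along(x$theta))),
    estimate = c(x$alpha, x$theta)
  )
}

#' @export
glance.ar_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, n = x$n, degenerate = x$degenerate)
}

#' Fit AR(2) models to all fittable segments of a subject
#'
#' @param segments Output of [segment_adjustments()].
#' @param lag Model order (default 2).
#' @return Tibble with one row per fittable segment: `trial_id`,
#'   `response_type`, `alpha`, `theta1`, `theta2`, `aic`, `n`. Unfittable
#'   segments are skipped and counted in the `n_skipped` attribute.
#' @export
fit_adjustments <- function(segments, lag = 2) {
  fit_rows <- segments[segments$fittable, , drop = FALSE]
  out <- purrr::map(seq_len(nrow(fit_rows)), function(i) {
    f <- fit_ar(fit_rows$series[[i]], lag = lag)
    tibble::tibble(
      trial_id = fit_rows$trial_id[i],
      response_type = fit_rows$response_type[i],
      alpha = f$alpha, theta1 = f$theta[1], theta2 = f$theta[2],
      aic = f$aic, n = f$n, y0 = fit_rows$series[[i]][1]
    )
  }) %>% bind_rows()
  if (nrow(fit_rows) == 0) {
    out <- tibble::tibble(trial_id = integer(), response_type = character(),
                          alpha = numeric(), theta1 = numeric(),
                          theta2 = numeric(), aic = numeric(), n = integer(),
                          y0 = numeric())
  }
  attr(out, "n_skipped") <- sum(!segments$fittable)
  out
}

#' Fit gaze adjustments for a whole cohort
#'
#' Preprocesses the sessions (pooled RT threshold), segments each subject's
#' trials and fits the AR(2) per segment.
#'
#' @param sessions List of [session_log()] objects.
#' @param config A [preprocess_config()].
#' @param lag AR order (default 2).
#' @return Tibble of per-segment fits with `subject_id` and `group` columns.
#' @export
fit_cohort_adjustments <- function(sessions, config = preprocess_config(),
                                   lag = 2) {
  pre <- preprocess_cohort(sessions, config)
  purrr::map2(pre$sessions, pre$trials, function(s, tr) {
    fits <- fit_adjustments(segment_adjustments(s, tr), lag = lag)
    mutate(fits, subject_id = s$subject_id, group = s$group, .before = 1)
  }) %>% bind_rows()
}

#' Average AR coefficients by group
#'
#' Arithmetic mean of each coefficient over fits, grouped by subject group
#' and — in `by_response_type` mode — by the four response types.
#'
#' @param fits Per-segment fit tibble with `group`, `response_type`,
#'   `alpha`, `theta1`, `theta2` columns (see [fit_cohort_adjustments()]).
#' @param mode `"mixed"` (pool all response types) or `"by_response_type"`.
#' @return Tibble of per-cell coefficient means with an `n_fits` count.
#' @export
average_coefficients <- function(fits, mode = c("mixed", "by_response_type")) {
  mode <- match.arg(mode)
  keys <- if (mode == "mixed") "group" else c("group", "response_type")
  fits %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      alpha = mean(.data$alpha), theta1 = mean(.data$theta1),
      theta2 = mean(.data$theta2), aic = mean(.data$aic),
      n_fits = dplyr::n(), .groups = "drop"
    )
}

#' Extrapolate average AR(2) dynamics
#'
#' Iterates `y_t = alpha + theta1 y_{t-1} + theta2 y_{t-2}` from
#' `y_1 = y_2 = init` for `horizon` steps. The gaze-adjustment velocity is
#' the mean of the negative first difference of the extrapolated series
#' (normalized units per step; positive when the distance shrinks, i.e. the
#' gaze approaches the stimulus). The per-second velocity `velocity / dt`
#' is also reported. Dynamics whose companion-matrix roots reach the unit
#' circle are flagged divergent.
#'
#' @param coeffs Numeric `c(alpha, theta1, theta2)`, or a one-row tibble
#'   with those columns (e.g. a row of [average_coefficients()]).
#' @param init Starting distance (both initial conditions), in
#'   `[0, sqrt(2)]`.
#' @param horizon Number of steps (>= 2, default 50 — about 700 ms at 72 Hz).
#' @param dt Sample interval in seconds (default `1/72`).
#' @return An `ar_extrapolation` object: `series`, `velocity`,
#'   `velocity_per_s`, `divergent`, `fixed_point`.
#' @export
extrapolate_ar <- function(coeffs, init = 0.5, horizon = 50, dt = 1 / 72) {
  if (is.data.frame(coeffs)) {
    coeffs <- c(coeffs$alpha[1], coeffs$theta1[1], coeffs$theta2[1])
  }
  if (horizon < 2) abort("`horizon` must be >= 2")
  alpha <- coeffs[1]; th1 <- coeffs[2]; th2 <- coeffs[3]
  y <- numeric(horizon)
  y[1] <- y[2] <- init
  for (t in 3:horizon) y[t] <- alpha + th1 * y[t - 1] + th2 * y[t - 2]
  roots <- eigen(matrix(c(th1, th2, 1, 0), 2, 2, byrow = TRUE),
                 only.values = TRUE)$values
  divergent <- any(Mod(roots) >= 1)
  if (divergent) warn("AR dynamics are non-stationary; extrapolation diverges")
  vel <- mean(-diff(y))
  structure(
    list(series = y, velocity = vel, velocity_per_s = vel / dt,
         divergent = divergent,
         fixed_point = if (abs(1 - th1 - th2) > 1e-12) {
           alpha / (1 - th1 - th2)
         } else NA_real_),
    class = "ar_extrapolation"
  )
}

#' @export
print.ar_extrapolation <- function(x, ...) {
  cat(sprintf(
    "<ar_extrapolation> %d steps, velocity %.4f per step (%.4f per s)%s\n",
    length(x$series), x$velocity, x$velocity_per_s,
    if (x$divergent) " [divergent]" else ""
  ))
  invisible(x)
}

#' Per-subject coefficient cells for classification
#'
#' Groups each subject's per-segment AR coefficients into cells — one cell
#' per subject in `mixed` mode, up to four (one per response type) in
#' `by_response_type` mode — ready for moment summarization. Cell contents
#' do not depend on segment order.
#'
#' @param fits Per-segment fit tibble (see [fit_cohort_adjustments()]).
#' @param mode `"mixed"` or `"by_response_type"`.
#' @return Tibble nested by subject (and response type), with list columns
#'   of `alpha`, `theta1`, `theta2` values per cell.
#' @export
adjustment_feature_table <- function(fits,
                                     mode = c("mixed", "by_response_type")) {
  mode <- match.arg(mode)
  keys <- if (mode == "mixed") c("subject_id", "group") else
    c("subject_id", "group", "response_type")
  fits %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      alpha = list(.data$alpha), theta1 = list(.data$theta1),
      theta2 = list(.data$theta2), n_fits = dplyr::n(), .groups = "drop"
    )
}
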
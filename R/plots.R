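# ggplot2 views of the main result types.

#' Plot a session's gaze track and stimuli
#'
#' Gaze path over the unit square, colored by time, with the stimulus
#' centers overlaid by kind.
#'
#' @param object A [session_log()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.session_log <- function(object, ...) {
  ggplot2::ggplot(object$gaze, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$t / 1000), alpha = 0.6) +
    ggplot2::geom_point(
      data = object$stimuli,
      ggplot2::aes(x = .data$cx, y = .data$cy, shape = .data$kind),
      size = 3, colour = "red", inherit.aes = FALSE
    ) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Subject %s (%s)", object$subject_id, object$group),
      colour = "time (s)", x = "x (normalized)", y = "y (normalized)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot extrapolated gaze-adjustment dynamics
#'
#' The extrapolated gaze-to-stimulus distance over steps (solid) and the
#' negative of its first difference — the gaze-adjustment velocity —
#' (dotted).
#'
#' @param object An `ar_extrapolation` from [extrapolate_ar()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ar_extrapolation <- function(object, ...) {
  n <- length(object$series)
  df <- dplyr::bind_rows(
    tibble::tibble(step = seq_len(n), value = object$series,
                   what = "distance"),
    tibble::tibble(step = 2:n, value = -diff(object$series),
                   what = "velocity")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   linetype = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(distance = "solid",
                                              velocity = "dotted")) +
    ggplot2::labs(
      title = sprintf("Extrapolated gaze adjustment (velocity %.4f/step)",
                      object$velocity),
      x = "step", y = "normalized distance", linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold classification metrics
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$folds[, c("fold", "accuracy", "mcc", "auc")],
    -"fold", names_to = "metric", values_to = "value"
  )
  df$value[df$metric == "accuracy"] <- df$value[df$metric == "accuracy"] / 100
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = "score (accuracy as fraction)") +
    ggplot2::theme_minimal()
}

#' Effect-size overview of a feature comparison
#'
#' Cohen's d per feature, flagged by Benjamini-Hochberg significance (both
#' test families surviving at the configured level).
#'
#' @param comparison Output of [compare_two_groups()].
#' @return A ggplot.
#' @export
plot_effect_sizes <- function(comparison) {
  df <- dplyr::arrange(comparison, .data$cohen_d)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohen_d, y = .data$feature,
                                   fill = .data$bh_significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-0.8, 0.8), linetype = "dashed") +
    ggplot2::labs(x = "Cohen's d (typical - clinical)", y = NULL,
                  fill = "BH significant") +
    ggplot2::theme_minimal()
}
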
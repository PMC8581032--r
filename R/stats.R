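# Group-comparison battery: pooled-variance Student t, Mann-Whitney U (with
# normal approximation and tie correction), Cohen's d with the
# typical-minus-clinical sign convention, one-way ANOVA for three groups,
# and Benjamini-Hochberg false-discovery-rate control over the feature
# family.

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled`, pooled SD
#' with one degree of freedom per group. By convention group `a` is the
#' typical group and `b` the clinical one, so a negative `d` means the
#' clinical group's mean is larger. `|d| > 0.8` is conventionally called a
#' large effect.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return Effect size `d`; `NA` (with a message) when the pooled SD is 0.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    inform("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up false-discovery-rate control: reject all hypotheses with
#' `p <= p_(k*)` where `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param pvals P-values in `[0, 1]` (`NA`s are never rejected).
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejection flags, aligned with `pvals`.
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(FALSE, length(pvals))
  ok <- !is.na(pvals)
  # p.adjust("BH") implements exactly the step-up rule
  out[ok] <- p.adjust(pvals[ok], method = "BH") <= q
  out
}

#' Two-group feature comparison battery
#'
#' For every feature column: pooled-variance Student t test (two-sided),
#' Mann-Whitney U test (two-sided, normal approximation with tie
#' correction), and Cohen's d with `group1` as the first group. The
#' Benjamini-Hochberg procedure is applied separately to the t and U
#' p-value families across the features tested in this run; a feature is
#' flagged `bh_significant` when both survive at level `q`.
#'
#' @param features Tibble with a `group` column and numeric feature columns
#'   (e.g. from [extract_cohort_features()]); non-feature id columns are
#'   ignored.
#' @param group1,group2 The two labels to compare. `group2` may be a vector
#'   of labels pooled into one clinical group (the default pools the two
#'   ASD subgroups).
#' @param q FDR level (default 0.05).
#' @param welch Use Welch's unequal-variance t instead of the pooled
#'   Student t (default `FALSE`).
#' @return Tibble with one row per feature: group means/SDs, `t`, `p_t`,
#'   `u`, `p_u`, `cohen_d`, BH flags. Features constant in both groups are
#'   skipped with a message.
#' @export
compare_two_groups <- function(features, group1 = "typical",
                               group2 = c("asd_no_adhd", "asd_adhd"),
                               q = 0.05, welch = FALSE) {
  stopifnot("group" %in% names(features))
  feat_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  ga <- features$group %in% group1
  gb <- features$group %in% group2
  if (sum(ga) < 2 || sum(gb) < 2) {
    abort("both groups must be present with at least 2 subjects each")
  }
  rows <- purrr::map(feat_cols, function(f) {
    a <- features[[f]][ga]; a <- a[!is.na(a)]
    b <- features[[f]][gb]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (sd(a) == 0 && sd(b) == 0)) {
      inform(sprintf("feature '%s' degenerate in both groups; tests skipped", f))
      return(tibble::tibble(
        feature = f, mean_1 = mean(a), sd_1 = sd_or_zero(a),
        mean_2 = mean(b), sd_2 = sd_or_zero(b),
        t = NA_real_, p_t = NA_real_, u = NA_real_, p_u = NA_real_,
        cohen_d = NA_real_
      ))
    }
    tt <- t.test(a, b, var.equal = !welch)
    ut <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    tibble::tibble(
      feature = f, mean_1 = mean(a), sd_1 = sd(a),
      mean_2 = mean(b), sd_2 = sd(b),
      t = unname(tt$statistic), p_t = tt$p.value,
      u = unname(ut$statistic), p_u = ut$p.value,
      cohen_d = cohens_d(a, b)
    )
  }) %>% bind_rows()
  rows$bh_significant_t <- benjamini_hochberg(rows$p_t, q)
  rows$bh_significant_u <- benjamini_hochberg(rows$p_u, q)
  rows$bh_significant <- rows$bh_significant_t & rows$bh_significant_u
  attr(rows, "q") <- q
  attr(rows, "family_size") <- sum(!is.na(rows$p_t))
  rows
}

#' Three-group one-way ANOVA per feature
#'
#' Fixed-effects one-way ANOVA p-value for each feature column across the
#' group labels present (each group needs at least 2 subjects). With two
#' groups this reduces to the squared pooled t statistic, `F = t^2`.
#'
#' @param features Tibble with a `group` column and numeric feature columns.
#' @param q FDR level for the BH flags (default 0.05).
#' @return Tibble with one row per feature: `f`, `p_anova`,
#'   `bh_significant`.
#' @export
anova_groups <- function(features, q = 0.05) {
  stopifnot("group" %in% names(features))
  counts <- table(features$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("each group must be present with at least 2 subjects")
  }
  feat_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  g <- factor(features$group)
  rows <- purrr::map(feat_cols, function(f) {
    x <- features[[f]]
    keep <- !is.na(x)
    if (length(unique(g[keep])) < 2 || sd(x[keep]) == 0) {
      return(tibble::tibble(feature = f, f_stat = NA_real_,
                            p_anova = NA_real_))
    }
    fit <- oneway.test(x[keep] ~ g[keep], var.equal = TRUE)
    tibble::tibble(feature = f, f_stat = unname(fit$statistic),
                   p_anova = fit$p.value)
  }) %>% bind_rows()
  rows$bh_significant <- benjamini_hochberg(rows$p_anova, q)
  rows
}

#' Two-group comparison of gaze-adjustment coefficients
#'
#' Compares the per-fit AR coefficients between groups. In `mixed` mode the
#' observations are subject-by-response-type cell means pooled over types
#' (so a 52-subject cohort contributes up to 208 observations); in
#' `by_response_type` mode each response type is tested separately. Cell
#' means within subjects are treated as independent observations, mirroring
#' the per-cell accounting of the protocol; this overstates the effective
#' sample size and is flagged here deliberately.
#'
#' @param fits Per-segment fit tibble (see [fit_cohort_adjustments()]).
#' @param group1,group2 Labels as in [compare_two_groups()].
#' @param mode `"mixed"` or `"by_response_type"`.
#' @param q FDR level.
#' @return Tibble of per-coefficient (and per-type) comparisons.
#' @export
compare_adjustment_groups <- function(fits, group1 = "typical",
                                      group2 = c("asd_no_adhd", "asd_adhd"),
                                      mode = c("mixed", "by_response_type"),
                                      q = 0.05) {
  mode <- match.arg(mode)
  cells <- fits %>%
    group_by(.data$subject_id, .data$group, .data$response_type) %>%
    summarise(alpha = mean(.data$alpha), theta1 = mean(.data$theta1),
              theta2 = mean(.data$theta2), .groups = "drop")
  run <- function(tbl, label) {
    out <- tryCatch(
      compare_two_groups(
        select(tbl, dplyr::all_of(c("group", "alpha", "theta1", "theta2"))),
        group1 = group1, group2 = group2, q = q
      ),
      error = function(e) {
        inform(sprintf("cell '%s' skipped: %s", label, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(out)) return(NULL)
    mutate(out, cell = label, .before = 1)
  }
  if (mode == "mixed") {
    run(cells, "mixed")
  } else {
    purrr::map(sort(unique(cells$response_type)), function(rt) {
      run(filter(cells, .data$response_type == rt), rt)
    }) %>% bind_rows()
  }
}
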
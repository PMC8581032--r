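# One-call orchestration: simulate -> preprocess -> spatial features ->
# AR adjustment fits -> group statistics -> classification, reproducible
# from a single seed.

#' Pipeline configuration
#'
#' Bundles every stage's settings. A single global `seed` deterministically
#' derives the cohort and classification seeds (drawn from one seeded
#' stream, in that order), so the whole report bundle is reproducible from
#' the config alone.
#'
#' @param seed Global seed.
#' @param schedule A [schedule_config()].
#' @param n_typical,n_asd_no_adhd,n_asd_adhd Cohort composition.
#' @param preprocess A [preprocess_config()].
#' @param entropy An [entropy_config()].
#' @param adjustment List: `horizon` (extrapolation steps, default 50) and
#'   `init` (`"cohort_mean"` of segment starting distances, or a number).
#' @param stats List: `q` (FDR level) and `welch` flag.
#' @param classify List: `mode` (see [assemble_input()]), `three_class`,
#'   `folds`, `significant`, `n_components`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            schedule = schedule_config(),
                            n_typical = 31, n_asd_no_adhd = 11,
                            n_asd_adhd = 10,
                            preprocess = preprocess_config(),
                            entropy = entropy_config(),
                            adjustment = list(horizon = 50,
                                              init = "cohort_mean"),
                            stats = list(q = 0.05, welch = FALSE),
                            classify = list(
                              mode = "response_type_gaze_significant",
                              three_class = FALSE, folds = 3,
                              significant = "fixed_list", n_components = 5
                            )) {
  structure(
    list(seed = seed, schedule = schedule, n_typical = n_typical,
         n_asd_no_adhd = n_asd_no_adhd, n_asd_adhd = n_asd_adhd,
         preprocess = preprocess, entropy = entropy,
         adjustment = adjustment, stats = stats, classify = classify),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `schedule`,
#' `preprocess` and `entropy` are maps passed to their constructors. Absent
#' keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "n_typical", "n_asd_no_adhd", "n_asd_adhd")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$schedule)) {
    args$schedule <- do.call(schedule_config, raw$schedule)
  }
  if (!is.null(raw$preprocess)) {
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$entropy)) args$entropy <- do.call(entropy_config, raw$entropy)
  base <- pipeline_config()
  for (k in c("adjustment", "stats", "classify")) {
    if (!is.null(raw[[k]])) {
      args[[k]] <- utils::modifyList(base[[k]], raw[[k]])
    }
  }
  do.call(pipeline_config, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, preprocesses it with a pooled RT threshold, extracts
#' the 24 spatial features per subject, fits per-trial AR(2) gaze-adjustment
#' models, averages and extrapolates the coefficients per group, runs the
#' two-group (and, when all three groups are present, three-group)
#' statistical battery, and evaluates the configured classification
#' modality under nested CV. Rerunning with the same config reproduces
#' every number in the bundle.
#'
#' @param config A [pipeline_config()] or a path to a YAML file for
#'   [pipeline_config_from_yaml()].
#' @param out_dir Optional directory; when given, the feature table,
#'   comparison reports, group-average coefficients, extrapolated
#'   velocities and the classification report are written there as
#'   CSV/JSON.
#' @return A `gazenogo_pipeline` list: `features`, `preprocess_report`,
#'   `threshold_ms`, `comparisons`, `anova`, `adjustment` (averages and
#'   per-group extrapolation velocities, mixed and by response type),
#'   `classification`, `log`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- pipeline_config_from_yaml(config)
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, 2))

  cohort <- with_stage("simulate", generate_cohort(
    cohort_spec(config$n_typical, config$n_asd_no_adhd, config$n_asd_adhd,
                seed = stage_seeds[1]),
    config$schedule
  ))

  features <- with_stage("features", extract_cohort_features(
    cohort, config = config$preprocess, entropy = config$entropy
  ))

  fits <- with_stage("adjust", fit_cohort_adjustments(
    cohort, config = config$preprocess
  ))

  comparisons <- with_stage("stats", compare_two_groups(
    select(features, -"subject_id"), q = config$stats$q,
    welch = config$stats$welch
  ))
  anova_tbl <- if (all(c("typical", "asd_no_adhd", "asd_adhd") %in%
                         features$group) &&
                     all(table(features$group) >= 2)) {
    with_stage("stats", anova_groups(select(features, -"subject_id"),
                                     q = config$stats$q))
  } else {
    NULL
  }
  adj_comparisons <- with_stage("stats", list(
    mixed = compare_adjustment_groups(fits, mode = "mixed",
                                      q = config$stats$q),
    by_response_type = compare_adjustment_groups(
      fits, mode = "by_response_type", q = config$stats$q
    )
  ))

  init <- if (identical(config$adjustment$init, "cohort_mean")) {
    if (nrow(fits) > 0) mean(fits$y0) else 0.5
  } else {
    config$adjustment$init
  }
  dt <- config$preprocess$downsample_factor / config$schedule$sample_rate_hz
  velocity_table <- function(avg) {
    avg$velocity <- vapply(seq_len(nrow(avg)), function(i) {
      extrapolate_ar(avg[i, ], init = init,
                     horizon = config$adjustment$horizon, dt = dt)$velocity
    }, numeric(1))
    avg
  }
  adjustment <- with_stage("adjust", list(
    averages_mixed = velocity_table(average_coefficients(fits, "mixed")),
    averages_by_type = velocity_table(
      average_coefficients(fits, "by_response_type")
    ),
    init = init, horizon = config$adjustment$horizon, dt = dt
  ))

  classification <- with_stage("classify", classify_cohort(
    features, fits, mode = config$classify$mode,
    three_class = isTRUE(config$classify$three_class),
    significant = config$classify$significant,
    grid = config$classify$grid %||% model_grid(),
    folds = config$classify$folds, seed = stage_seeds[2],
    n_components = config$classify$n_components
  ))

  result <- structure(
    list(
      features = features,
      preprocess_report = attr(features, "preprocess_report"),
      threshold_ms = attr(features, "threshold_ms"),
      comparisons = comparisons, anova = anova_tbl,
      adjustment_comparisons = adj_comparisons,
      adjustment = adjustment,
      classification = classification,
      log = list(
        seed = config$seed, stage_seeds = stage_seeds,
        n_subjects = length(cohort),
        n_fits = nrow(fits),
        threshold_ms = attr(features, "threshold_ms"),
        fraction_rt_removed = with(attr(features, "preprocess_report"),
                                   sum(n_removed) / max(sum(n_responses), 1))
      ),
      config = config
    ),
    class = "gazenogo_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$features, file.path(out_dir, "features.csv"))
  readr::write_csv(result$comparisons, file.path(out_dir, "comparisons.csv"))
  if (!is.null(result$anova)) {
    readr::write_csv(result$anova, file.path(out_dir, "anova.csv"))
  }
  readr::write_csv(result$adjustment$averages_by_type,
                   file.path(out_dir, "adjustment_coefficients.csv"))
  cls <- result$classification
  jsonlite::write_json(
    list(summary = glance(cls), folds = tidy(cls),
         confusion_pct = as.data.frame(cls$confusion_pct)),
    file.path(out_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.gazenogo_pipeline <- function(x, ...) {
  cat(sprintf(
    "<gazenogo_pipeline> %d subjects, RT threshold %.1f ms (%.1f%% removed)\n",
    nrow(x$features), x$threshold_ms, 100 * x$log$fraction_rt_removed
  ))
  cat(sprintf("  BH-significant spatial features: %d of %d\n",
              sum(x$comparisons$bh_significant, na.rm = TRUE),
              nrow(x$comparisons)))
  cat(sprintf("  classification (%s): accuracy %.1f%%, MCC %.2f, AUC %.2f\n",
              x$config$classify$mode, x$classification$accuracy,
              x$classification$mcc, x$classification$auc))
  invisible(x)
}
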
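test_that("schedule gaps stay within appearance + wait bounds and tile the session", {
  cfg <- schedule_config()
  for (seed in 1:3) {
    sch <- generate_stimulus_schedule(cfg, seed = seed)
    gaps <- diff(sch$onset)
    expect_true(all(gaps >= 1400 & gaps <= 1700))
    expect_gte(nrow(sch), 141)
    expect_lte(nrow(sch), 171)
    expect_lte(max(sch$offset), cfg$duration)
    expect_lte(sum(gaps), cfg$duration)
    expect_true(all(sch$location %in% 0:8))
    expect_equal(sum(sch$kind == "go"), round(nrow(sch) / 2))
  }
})

test_that("a too-short session yields an empty schedule", {
  sch <- generate_stimulus_schedule(schedule_config(duration = 0), seed = 1)
  expect_equal(nrow(sch), 0)
})

test_that("noise-free high-gain pursuit locks onto the stimulus", {
  cfg <- schedule_config(duration = 5000)
  sch <- generate_stimulus_schedule(cfg, seed = 2)
  prof <- subject_profile(gaze_gain = 0.999, gaze_latency = 0,
                          gaze_noise_sd = 0, p_anticipatory = 0)
  s <- simulate_session(prof, sch, cfg, seed = 3)
  # distance to stimulus center from a few samples after onset is ~0
  for (i in seq_len(nrow(sch))) {
    idx <- which(s$gaze$t >= sch$onset[i] + 60 & s$gaze$t < sch$offset[i])
    d <- sqrt((s$gaze$x[idx] - sch$cx[i])^2 + (s$gaze$y[idx] - sch$cy[i])^2)
    expect_lt(max(d), 1e-3)
  }
})

test_that("deterministic responders classify as 100% Go- and NoGo-positive", {
  cfg <- schedule_config(duration = 20000)
  sch <- generate_stimulus_schedule(cfg, seed = 4)
  prof <- subject_profile(p_go_respond = 1, p_nogo_inhibit = 1,
                          p_anticipatory = 0)
  trials <- classify_responses(simulate_session(prof, sch, cfg, seed = 5))
  stats <- response_stats(trials)
  expect_equal(stats$go_pos_pct, 100)
  expect_equal(stats$nogo_pos_pct, 100)
})

test_that("simulation is seed-deterministic", {
  cfg <- schedule_config(duration = 10000)
  sch <- generate_stimulus_schedule(cfg, seed = 6)
  prof <- group_presets()$asd_no_adhd
  a <- simulate_session(prof, sch, cfg, seed = 7)
  b <- simulate_session(prof, sch, cfg, seed = 7)
  c <- simulate_session(prof, sch, cfg, seed = 8)
  expect_true(session_logs_equal(a, b, tol = 0))
  expect_false(isTRUE(all.equal(a$responses$t, c$responses$t)))
})

test_that("cohorts have the requested composition and are reproducible", {
  cfg <- schedule_config(duration = 5000)
  cohort <- generate_cohort(cohort_spec(31, 11, 10, seed = 7), cfg)
  expect_length(cohort, 52)
  groups <- vapply(cohort, function(s) s$group, character(1))
  expect_equal(unname(table(groups)[c("typical", "asd_no_adhd", "asd_adhd")]),
               c(31, 11, 10), ignore_attr = TRUE)

  small <- generate_cohort(cohort_spec(2, 0, 0, seed = 1), cfg)
  expect_length(small, 2)
  expect_true(all(vapply(small, function(s) s$group, character(1)) == "typical"))

  again <- generate_cohort(cohort_spec(2, 0, 0, seed = 1), cfg)
  expect_true(session_logs_equal(small[[1]], again[[1]], tol = 0))

  expect_error(cohort_spec(-1, 0, 0), ">= 0")
})

test_that("generated logs pass strict validation", {
  cfg <- schedule_config(duration = 8000)
  cohort <- generate_cohort(cohort_spec(2, 1, 1, seed = 9), cfg)
  for (s in cohort) expect_s3_class(validate_session_log(s, strict = TRUE),
                                    "session_log")
})

test_that("injected group contrasts point the expected way (seed-averaged)", {
  # ASD presets: higher gaze-to-stimulus sample entropy, shorter dwell
  cfg <- schedule_config(duration = 30000)
  sen_t <- sen_a <- fix_t <- fix_a <- numeric()
  for (seed in 1:10) {
    cohort <- generate_cohort(cohort_spec(3, 2, 1, seed = seed), cfg)
    f <- suppressMessages(extract_cohort_features(cohort))
    typ <- f$group == "typical"
    sen_t <- c(sen_t, mean(f$gaze_obj_sen[typ], na.rm = TRUE))
    sen_a <- c(sen_a, mean(f$gaze_obj_sen[!typ], na.rm = TRUE))
    fix_t <- c(fix_t, mean(f$fixation_avg[typ], na.rm = TRUE))
    fix_a <- c(fix_a, mean(f$fixation_avg[!typ], na.rm = TRUE))
  }
  expect_gt(mean(sen_a), mean(sen_t))
  expect_lt(mean(fix_a), mean(fix_t))
})
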
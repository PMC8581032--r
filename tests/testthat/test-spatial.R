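test_that("trajectory area matches known polygons and a hull oracle", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(trajectory_area(sq), 1)
  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1))
  expect_equal(trajectory_area(tri), 0.5)
  expect_equal(trajectory_area(data.frame(x = rep(0.3, 5), y = rep(0.7, 5))), 0)
  expect_equal(trajectory_area(data.frame(x = c(0, 0.5, 1), y = c(0, 0.5, 1))), 0)

  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:30, 1)
    x <- runif(n)
    y <- runif(n)
    expect_equal(trajectory_area(data.frame(x = x, y = y)),
                 hull_area_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("kinematics recover analytic velocity and acceleration", {
  rate <- 72
  n <- 200
  still <- tibble::tibble(x = rep(0.4, n), y = rep(0.6, n))
  k0 <- kinematics(still, rate)
  expect_equal(k0$v, rep(0, n), tolerance = 1e-9)
  expect_equal(k0$a, rep(0, n), tolerance = 1e-9)

  # uniform motion: 0.05 units/s in x, 0.02 in y -> speed sqrt(29)/100
  t <- (seq_len(n) - 1) / rate
  lin <- tibble::tibble(x = 0.1 + 0.05 * t, y = 0.2 + 0.02 * t)
  kl <- kinematics(lin, rate)
  inner <- 3:(n - 2)
  expect_equal(kl$v[inner], rep(sqrt(0.05^2 + 0.02^2), length(inner)),
               tolerance = 1e-6)
  expect_equal(kl$a[inner], rep(0, length(inner)), tolerance = 1e-6)

  # smooth sinusoid vs central differences
  sine <- tibble::tibble(x = 0.5 + 0.2 * sin(2 * pi * 0.5 * t), y = rep(0.5, n))
  ks <- kinematics(sine, rate)
  cd <- abs((sine$x[inner + 1] - sine$x[inner - 1]) * rate / 2)
  expect_lt(max(abs(ks$v[inner] - cd) / max(cd)), 0.01)
})

test_that("step distance and angle follow the position-vector geometry", {
  g <- data.frame(x = c(1, 0), y = c(0, 1))
  sda <- step_distance_angle(g)
  expect_equal(sda$distance, sqrt(2))
  expect_equal(sda$angle, pi / 2)

  same <- step_distance_angle(data.frame(x = c(0.3, 0.3), y = c(0.3, 0.3)))
  expect_equal(same$distance, 0)
  expect_equal(same$angle, 0)

  diag45 <- step_distance_angle(data.frame(x = c(1, 1), y = c(0, 1)))
  expect_equal(diag45$distance, 1)
  expect_equal(diag45$angle, pi / 4)

  expect_message(
    z <- step_distance_angle(data.frame(x = c(0, 1), y = c(0, 0))),
    "zero-magnitude"
  )
  expect_equal(z$angle, 0)
})

test_that("gaze-object difference covers exactly the stimulus-on samples", {
  n <- 300
  s <- make_session(rep(0.5, n), rep(0.5, n),
                    one_go_stimulus(onset = 500, offset = 1200,
                                    cx = 0.75, cy = 0.5))
  god <- gaze_object_difference(s)
  n_in <- sum(s$gaze$t >= 500 & s$gaze$t < 1200)
  expect_equal(nrow(god), n_in)
  expect_equal(god$dx, rep(-0.25, n_in))
  expect_equal(god$dy, rep(0, n_in))
})

test_that("fixation dwell integrates time inside the stimulus circle", {
  rate <- 144
  n <- 300
  # gaze pinned to the center the whole appearance
  s <- make_session(rep(0.5, n), rep(0.5, n), one_go_stimulus())
  f <- fixation_times(s)
  expect_equal(f$fixation_avg, 700, tolerance = 1000 / rate)

  # enters the 0.25 circle at onset+200 and leaves at onset+500
  t <- (seq_len(n) - 1) * 1000 / rate
  x <- ifelse(t >= 200 & t < 500, 0.5, 0.9)
  s2 <- make_session(x, rep(0.5, n), one_go_stimulus())
  f2 <- fixation_times(s2)
  expect_equal(f2$fixation_avg, 300, tolerance = 2 * 1000 / rate)

  # never inside
  s3 <- make_session(rep(0.05, n), rep(0.95, n),
                     one_go_stimulus(cx = 0.8, cy = 0.2))
  expect_equal(fixation_times(s3)$fixation_avg, 0)

  # first-interval mode stops at the first exit
  x4 <- ifelse((t >= 100 & t < 200) | (t >= 400 & t < 600), 0.5, 0.9)
  s4 <- make_session(x4, rep(0.5, n), one_go_stimulus())
  expect_equal(fixation_times(s4, mode = "first_interval")$fixation_avg, 100,
               tolerance = 2 * 1000 / rate)
  expect_equal(fixation_times(s4, mode = "total")$fixation_avg, 300,
               tolerance = 2 * 1000 / rate)
})

test_that("the extractor emits exactly the 24 named attributes", {
  cfg <- schedule_config(duration = 20000)
  sch <- generate_stimulus_schedule(cfg, seed = 31)
  s <- simulate_session(group_presets()$typical, sch, cfg, seed = 32)
  pre <- preprocess_session(s)
  fv <- suppressMessages(extract_spatial_features(pre$session, pre$trials))
  expect_equal(setdiff(names(fv), c("subject_id", "group")),
               spatial_feature_names())
  expect_length(spatial_feature_names(), 24)
  vals <- unlist(fv[, spatial_feature_names()])
  pcts <- vals[c("go_pos_pct", "go_neg_pct", "nogo_pos_pct", "nogo_neg_pct")]
  expect_true(all(pcts >= 0 & pcts <= 100))
  ent <- vals[c("spatial_en", "gaze_obj_en", "gaze_obj_spe")]
  expect_true(all(ent >= 0 & ent <= 1, na.rm = TRUE))
  expect_true(all(vals[c("distance_sen", "angle_sen", "velocity_sen",
                         "gaze_obj_sen")] >= 0, na.rm = TRUE))
  expect_true(vals["trajectory_area"] >= 0 && vals["trajectory_area"] <= 1)
})

test_that("features are invariant to a disk round trip", {
  cfg <- schedule_config(duration = 15000)
  sch <- generate_stimulus_schedule(cfg, seed = 33)
  s <- simulate_session(group_presets()$typical, sch, cfg, seed = 34)
  p <- withr::local_tempdir()
  write_session_log(s, p)
  s2 <- read_session_log(p, strict = TRUE)
  pre1 <- preprocess_session(s)
  pre2 <- preprocess_session(s2)
  f1 <- suppressMessages(extract_spatial_features(pre1$session, pre1$trials))
  f2 <- suppressMessages(extract_spatial_features(pre2$session, pre2$trials))
  expect_equal(as.data.frame(f1[, -1]), as.data.frame(f2[, -1]),
               tolerance = 1e-8)
})

test_that("a noise-free lock-on session hits the degenerate feature limits", {
  cfg <- schedule_config(duration = 15000)
  sch <- generate_stimulus_schedule(cfg, seed = 35)
  prof <- subject_profile(gaze_gain = 0.999, gaze_latency = 0,
                          gaze_noise_sd = 0, p_anticipatory = 0)
  s <- simulate_session(prof, sch, cfg, seed = 36)
  pre <- preprocess_session(s)
  fv <- suppressMessages(extract_spatial_features(pre$session, pre$trials))
  expect_true(is.na(fv$gaze_obj_sen) || fv$gaze_obj_sen < 0.05)
  expect_equal(fv$fixation_avg, 700, tolerance = 3 * 1000 / 72)
})

test_that("more gaze noise raises the sample-entropy features (seed-averaged)", {
  cfg <- schedule_config(duration = 30000)
  ent <- function(noise_sd) {
    out <- sapply(1:5, function(seed) {
      sch <- generate_stimulus_schedule(cfg, seed = seed)
      prof <- subject_profile(gaze_noise_sd = noise_sd)
      s <- simulate_session(prof, sch, cfg, seed = 100 + seed)
      pre <- preprocess_session(s)
      fv <- suppressMessages(extract_spatial_features(pre$session, pre$trials))
      c(fv$distance_sen, fv$angle_sen, fv$gaze_obj_sen)
    })
    rowMeans(out)
  }
  lo <- ent(0.005)
  hi <- ent(0.02)
  expect_true(all(hi > lo))
})
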
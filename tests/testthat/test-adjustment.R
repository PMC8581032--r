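test_that("segments track trials, start at the onset distance, and stay in [0, sqrt(2)]", {
  cfg <- schedule_config(duration = 20000)
  sch <- generate_stimulus_schedule(cfg, seed = 41)
  s <- simulate_session(group_presets()$typical, sch, cfg, seed = 42)
  pre <- preprocess_session(s)
  trials <- pre$trials
  seg <- segment_adjustments(pre$session, trials)
  expect_equal(nrow(seg), nrow(trials))
  expect_equal(seg$response_type, trials$response_type)
  for (i in seq_len(nrow(seg))) {
    v <- seg$series[[i]]
    expect_true(all(v >= 0 & v <= sqrt(2)))
    g <- pre$session$gaze
    idx <- which(g$t >= trials$onset[i])[1]
    d0 <- sqrt((g$x[idx] - trials$cx[i])^2 + (g$y[idx] - trials$cy[i])^2)
    expect_equal(v[1], d0)
  }
  # pressed trials truncate at the response
  pressed <- which(!is.na(trials$rt) & trials$rt < 700)
  full <- which(is.na(trials$rt))
  if (length(pressed) > 0 && length(full) > 0) {
    expect_lt(min(seg$n[pressed]), max(seg$n[full]))
  }
})

test_that("a noise-free lock-on segment decays to zero within a few samples", {
  cfg <- schedule_config(duration = 10000)
  sch <- generate_stimulus_schedule(cfg, seed = 43)
  prof <- subject_profile(gaze_gain = 0.999, gaze_latency = 0,
                          gaze_noise_sd = 0, p_anticipatory = 0,
                          p_go_respond = 0, p_nogo_inhibit = 1)
  s <- simulate_session(prof, sch, cfg, seed = 44)
  seg <- segment_adjustments(s, classify_responses(s))
  for (v in seg$series[seg$n > 10]) expect_lt(max(tail(v, -5)), 1e-3)
})

test_that("AR(2) fits are exactly identifiable on noise-free series", {
  y <- ar2_gen(15, alpha = 0.1, th1 = 0.5, th2 = 0.3, sd = 0,
               y0 = 0.9, y1 = 0.2)
  f <- fit_ar(y)
  expect_equal(f$alpha, 0.1, tolerance = 1e-8)
  expect_equal(f$theta, c(0.5, 0.3), tolerance = 1e-8)
  expect_length(tidy(f)$estimate, 3)
})

test_that("AR coefficients equal the closed-form normal-equations oracle", {
  set.seed(45)
  y <- cumsum(rnorm(40, 0, 0.1))
  f <- fit_ar(y)
  n <- length(y)
  X <- cbind(1, y[2:(n - 1)], y[1:(n - 2)])
  b <- solve(t(X) %*% X, t(X) %*% y[3:n])
  expect_equal(c(f$alpha, f$theta), as.numeric(b), tolerance = 1e-10)
  resid <- y[3:n] - X %*% b
  n_eff <- n - 2
  expect_equal(f$aic, n_eff * log(sum(resid^2) / n_eff) + 6, tolerance = 1e-10)
  expect_error(fit_ar(y[1:5]), "too short")
})

test_that("noisy AR(2) parameter recovery is accurate on average", {
  set.seed(46)
  errs <- replicate(50, {
    y <- ar2_gen(50, alpha = 0.05, th1 = 0.5, th2 = 0.3, sd = 0.01,
                 y0 = runif(1, 0.2, 0.8), y1 = runif(1, 0.2, 0.8))
    f <- fit_ar(y)
    mean(abs(c(f$alpha - 0.05, f$theta - c(0.5, 0.3))))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("degenerate constant series are flagged and still fit", {
  expect_message(f <- fit_ar(rep(0.4, 20)), "rank-deficient")
  expect_true(f$degenerate)
  # alpha + (theta1 + theta2) * 0.4 must reproduce 0.4
  expect_equal(f$alpha + sum(f$theta) * 0.4, 0.4, tolerance = 1e-8)
})

test_that("coefficient averaging is the arithmetic mean per grouping cell", {
  fits <- tibble::tibble(
    subject_id = c("a", "a", "b"), group = "typical",
    response_type = c("go_pos", "go_neg", "go_pos"),
    alpha = c(0, 0.2, 0.1), theta1 = c(0.4, 0.6, 0.5),
    theta2 = c(0.2, 0.0, 0.1), aic = -5, n = 20, y0 = 0.5
  )
  single <- average_coefficients(fits[1, ], "mixed")
  expect_equal(c(single$alpha, single$theta1, single$theta2), c(0, 0.4, 0.2))

  two <- average_coefficients(fits[1:2, ], "mixed")
  expect_equal(c(two$alpha, two$theta1, two$theta2), c(0.1, 0.5, 0.1))

  mixed <- average_coefficients(fits, "mixed")
  split <- average_coefficients(fits, "by_response_type")
  expect_equal(sum(mixed$n_fits), sum(split$n_fits))
  expect_true(all(split$n_fits <= mixed$n_fits))
})

test_that("extrapolation reaches the fixed point and measures approach velocity", {
  ex <- extrapolate_ar(c(0.2, 0.5, 0.1), init = 0.9, horizon = 200)
  expect_false(ex$divergent)
  expect_equal(ex$fixed_point, 0.5)
  expect_equal(tail(ex$series, 1), 0.5, tolerance = 1e-6)
  # decreasing approach -> positive velocity; velocity is mean(-diff)
  expect_gt(ex$velocity, 0)
  expect_equal(ex$velocity, mean(-diff(ex$series)))
  expect_equal(ex$velocity_per_s, ex$velocity * 72)

  # neutrally stable identity dynamics: constant series, velocity 0
  expect_warning(flat <- extrapolate_ar(c(0, 1, 0), init = 0.4, horizon = 50),
                 "non-stationary")
  expect_equal(flat$series, rep(0.4, 50))
  expect_equal(flat$velocity, 0)
  expect_true(flat$divergent)
})

test_that("extrapolating an exact-generator fit recovers the generator's fixed point", {
  set.seed(47)
  y <- ar2_gen(400, alpha = 0.08, th1 = 0.6, th2 = 0.2, sd = 0.005)
  f <- fit_ar(y)
  ex <- extrapolate_ar(c(f$alpha, f$theta), init = 0.9, horizon = 500)
  expect_equal(tail(ex$series, 1), 0.08 / (1 - 0.8), tolerance = 0.05)
  true_fp <- extrapolate_ar(c(0.08, 0.6, 0.2), init = 0.9, horizon = 800)
  expect_equal(tail(true_fp$series, 1), 0.4, tolerance = 1e-6)
})

test_that("feature cells are grouping-correct and order-invariant", {
  fits <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 4), group = "typical",
    response_type = rep(c("go_pos", "go_neg", "nogo_pos", "nogo_neg"), 2),
    alpha = runif(8), theta1 = runif(8), theta2 = runif(8),
    aic = -5, n = 20, y0 = 0.5
  )
  mixed <- adjustment_feature_table(fits, "mixed")
  expect_equal(nrow(mixed), 2)
  split <- adjustment_feature_table(fits, "by_response_type")
  expect_equal(nrow(split), 8)

  perm <- adjustment_feature_table(fits[sample(8), ], "by_response_type")
  a_go <- sort(split$alpha[split$subject_id == "a" &
                             split$response_type == "go_pos"][[1]])
  b_go <- sort(perm$alpha[perm$subject_id == "a" &
                            perm$response_type == "go_pos"][[1]])
  expect_equal(a_go, b_go)
})
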
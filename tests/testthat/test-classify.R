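test_that("moment summaries match closed-form formulas and conventions", {
  x <- c(1, 2, 3, 4)
  m <- c(mean(x), sd(x))
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  skew <- mean((x - mu)^3) / s2^1.5
  kurt <- mean((x - mu)^4) / s2^2 - 3
  fits <- tibble::tibble(
    subject_id = "a", group = "typical", response_type = "go_pos",
    alpha = x, theta1 = x, theta2 = x, aic = -5, n = 20, y0 = 0.5
  )
  sm <- summarize_adjustment(fits, "mixed")
  expect_equal(ncol(sm), 2 + 12)
  expect_equal(sm$mixed_alpha_skew, skew)
  expect_equal(sm$mixed_alpha_kurt, kurt)
  expect_equal(sm$mixed_alpha_mean, mu)
  expect_equal(sm$mixed_alpha_sd, sd(x))

  # constant cell: shape moments are 0 by convention
  fits$alpha <- 2
  smc <- summarize_adjustment(fits, "mixed")
  expect_equal(smc$mixed_alpha_skew, 0)
  expect_equal(smc$mixed_alpha_kurt, 0)
  expect_equal(smc$mixed_alpha_mean, 2)
  expect_equal(smc$mixed_alpha_sd, 0)
})

test_that("by-response-type summaries have the 48-value layout with NA empty cells", {
  fits <- tibble::tibble(
    subject_id = rep(c("a", "b"), c(4, 2)), group = "typical",
    response_type = c("go_pos", "go_neg", "nogo_pos", "nogo_neg",
                      "go_pos", "go_pos"),
    alpha = runif(6), theta1 = runif(6), theta2 = runif(6),
    aic = -5, n = 20, y0 = 0.5
  )
  sm <- summarize_adjustment(fits, "by_response_type")
  expect_equal(ncol(sm), 2 + 4 * 3 * 4)
  expect_equal(nrow(sm), 2)
  # subject b never produced a go_neg trial -> that cell is missing
  expect_true(is.na(sm$go_neg_alpha_mean[sm$subject_id == "b"]))
  expect_false(is.na(sm$go_pos_alpha_mean[sm$subject_id == "b"]))
})

test_that("NCA retains the requested dimension and helps a 1-NN classifier", {
  set.seed(61)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "a", -2, 2) + rnorm(n, 0, 0.5),
             matrix(rnorm(n * 9, 0, 3), n, 9))
  Xs <- scale(X)
  tr <- c(1:20, 31:50)
  te <- setdiff(1:n, tr)

  red <- reduce_nca(Xs[tr, ], y[tr], n_components = 5)
  expect_equal(ncol(red$X), 5)
  expect_equal(nrow(red$X), length(tr))

  red2 <- reduce_nca(Xs[tr, ], y[tr], n_components = 5)
  expect_identical(red$fit$A, red2$fit$A)

  acc_raw <- mean(knn1(Xs[tr, ], y[tr], Xs[te, ]) == y[te])
  acc_red <- mean(knn1(red$X, y[tr], predict(red$fit, Xs[te, ])) == y[te])
  expect_gte(acc_red, acc_raw)

  expect_error(nca_fit(Xs[, 1:3], y, n_components = 5), "rank")
})

test_that("MCC matches the formula oracle and its conventions", {
  expect_equal(mcc(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(mcc(matrix(c(0, 10, 10, 0), 2)), -1)

  # counts reconstructed from row percentages of a 31/21 cohort
  cm <- matrix(c(26, 1, 5, 20), 2, 2)  # TN 26, FN 1, FP 5, TP 20
  expect_equal(mcc(cm), 515 / sqrt(25 * 21 * 31 * 27))

  set.seed(62)
  for (i in 1:10) {
    tp <- sample(1:50, 1); tn <- sample(1:50, 1)
    fp <- sample(1:50, 1); fn <- sample(1:50, 1)
    oracle <- (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(mcc(matrix(c(tn, fn, fp, tp), 2, 2)), oracle)
  }

  # random labels: MCC near zero
  set.seed(63)
  a <- sample(c("x", "y"), 4000, replace = TRUE)
  p <- sample(c("x", "y"), 4000, replace = TRUE)
  expect_lt(abs(mcc(confusion_matrix(a, p))), 0.05)

  expect_message(m0 <- mcc(matrix(c(5, 3, 0, 0), 2, 2)), "degenerate")
  expect_equal(m0, 0)
})

test_that("stratified folds keep every class in every fold", {
  y <- rep(c("a", "b", "c"), c(12, 7, 5))
  f <- stratified_folds(y, 3, seed = 64)
  for (k in 1:3) expect_setequal(unique(y[f == k]), c("a", "b", "c"))
  expect_identical(f, stratified_folds(y, 3, seed = 64))
  expect_error(stratified_folds(c("a", "a", "b"), 3), "at least 3")
})

test_that("AdaBoost separates separable data and predicts proper probabilities", {
  set.seed(65)
  n <- 40
  y <- rep(c("neg", "pos"), each = n / 2)
  X <- cbind(ifelse(y == "pos", 1, -1) + rnorm(n, 0, 0.2),
             rnorm(n), rnorm(n))
  m <- adaboost_fit(X, y, n_estimators = 25, max_depth = 1, max_leaf = 3,
                    feature_fraction = 1, seed = 66)
  expect_equal(mean(predict(m, X, type = "class") == y), 1)
  p <- predict(m, X, type = "prob")
  expect_equal(rowSums(p), rep(1, n))
  expect_true(all(p >= 0 & p <= 1))
  # staged prefix uses only the first rounds
  p1 <- predict(m, X, type = "prob", n_estimators = 1)
  expect_true(all(p1 %in% c(0, 1)))
})

test_that("nested CV is perfect on separable cohorts and seed-deterministic", {
  set.seed(67)
  n <- 36
  y <- rep(c("typical", "asd"), each = n / 2)
  X <- cbind(ifelse(y == "asd", 2, -2) + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 3), n, 3))
  small_grid <- model_grid(max_depth = c(1, 3), max_leaf = 3,
                           n_estimators = c(15, 25), learning_rate = 0.5)
  rep_ <- train_eval_cv(X, factor(y, c("typical", "asd")), grid = small_grid,
                        seed = 68, positive = "asd")
  expect_equal(rep_$accuracy, 100)
  expect_equal(rep_$mcc, 1)
  expect_equal(rep_$auc, 1)
  expect_equal(unname(diag(rep_$confusion_pct)), c(100, 100))

  rep2 <- train_eval_cv(X, factor(y, c("typical", "asd")), grid = small_grid,
                        seed = 68, positive = "asd")
  expect_identical(glance(rep_), glance(rep2))
  expect_equal(nrow(tidy(rep_)), 3)
})

test_that("label-shuffled nulls score near the majority rate", {
  set.seed(69)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5)
  tiny_grid <- model_grid(max_depth = 1, max_leaf = 3, n_estimators = 15,
                          learning_rate = 0.5)
  accs <- sapply(1:10, function(s) {
    y <- sample(rep(c("typical", "asd"), c(18, 12)))
    train_eval_cv(X, factor(y, c("typical", "asd")), grid = tiny_grid,
                  seed = s, positive = "asd")$accuracy
  })
  expect_lt(abs(mean(accs) - 60), 12)
})

test_that("no leakage: a label-copy feature shuffled in held-out rows cannot score", {
  set.seed(70)
  n <- 30
  y <- factor(rep(c("typical", "asd"), each = n / 2), c("typical", "asd"))
  X <- cbind(leak = as.numeric(y) + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 3), n, 3))
  seed <- 71
  fold_id <- stratified_folds(y, 3, seed = seed)
  for (f in 1:3) {
    idx <- which(fold_id == f)
    X[idx, 1] <- sample(X[idx, 1])
  }
  tiny_grid <- model_grid(max_depth = 1, max_leaf = 3, n_estimators = 15,
                          learning_rate = 0.5)
  rep_ <- train_eval_cv(X, y, grid = tiny_grid, seed = seed,
                        positive = "asd")
  expect_lt(rep_$accuracy, 95)
  expect_lt(rep_$auc, 0.95)
})

test_that("assembled inputs have the documented column contracts", {
  cfg <- schedule_config(duration = 15000)
  cohort <- generate_cohort(cohort_spec(4, 2, 2, seed = 72), cfg)
  spatial <- suppressMessages(extract_cohort_features(cohort))
  fits <- fit_cohort_adjustments(cohort)

  sp <- assemble_input(summarize_adjustment(fits, "mixed"), spatial,
                       mode = "spatial")
  expect_equal(ncol(sp), 24)
  expect_equal(colnames(sp), spatial_feature_names())

  ga <- assemble_input(summarize_adjustment(fits, "mixed"), spatial,
                       mode = "gaze_adjustment")
  expect_equal(ncol(ga), 5)

  by_type <- summarize_adjustment(fits, "by_response_type")
  rtg <- assemble_input(by_type, spatial, mode = "response_type_gaze")
  expect_equal(ncol(rtg), 5)

  sig <- assemble_input(by_type, spatial,
                        mode = "response_type_gaze_significant")
  expect_equal(ncol(sig), 13)

  perf <- assemble_input(by_type, spatial,
                         mode = "response_type_gaze_significant_performance")
  expect_equal(ncol(perf), 19)
  expect_true(all(colnames(sig) %in% colnames(perf)))
  expect_true(all(colnames(rtg) %in% colnames(sig)))
})
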
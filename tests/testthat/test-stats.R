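test_that("Cohen's d follows the pooled-SD definition and sign convention", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_message(dd <- cohens_d(rep(2, 3), rep(2, 4)), "undefined")
  expect_true(is.na(dd))
})

test_that("Benjamini-Hochberg matches hand-computed step-up thresholds", {
  # thresholds 0.0125 / 0.025 / 0.0375 / 0.05
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(benjamini_hochberg(rep(1, 6)), rep(FALSE, 6))
  expect_equal(benjamini_hochberg(rep(0, 6)), rep(TRUE, 6))
})

test_that("BH flags equal the exhaustive prefix oracle for random families", {
  set.seed(51)
  for (rep in 1:20) {
    m <- sample(1:50, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(benjamini_hochberg(p, q), bh_oracle(p, q),
                 label = sprintf("rep %d (m=%d q=%g)", rep, m, q))
  }
})

test_that("ANOVA hits the identity and separation limits, and F = t^2 for two groups", {
  g3 <- tibble::tibble(
    group = rep(c("typical", "asd_no_adhd", "asd_adhd"), each = 5),
    f1 = rep(c(1, 2, 3, 4, 5), 3)
  )
  a <- anova_groups(g3)
  expect_equal(a$f_stat, 0)
  expect_equal(a$p_anova, 1)

  g3$f1[g3$group == "asd_adhd"] <- g3$f1[g3$group == "asd_adhd"] +
    3 * sd(c(1, 2, 3, 4, 5))
  expect_lt(anova_groups(g3)$p_anova, 0.001)

  set.seed(52)
  g2 <- tibble::tibble(group = rep(c("typical", "asd_no_adhd"), each = 8),
                       f1 = rnorm(16))
  a2 <- anova_groups(g2)
  t2 <- t.test(f1 ~ group, data = g2, var.equal = TRUE)
  expect_equal(a2$f_stat, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p_anova, t2$p.value, tolerance = 1e-10)
})

test_that("the two-group battery reports both tests with the typical-first sign", {
  set.seed(53)
  tbl <- tibble::tibble(
    group = rep(c("typical", "asd_no_adhd"), each = 10),
    low_in_asd = c(rnorm(10, 5), rnorm(10, 3)),
    high_in_asd = c(rnorm(10, 0), rnorm(10, 2)),
    null_feat = rnorm(20)
  )
  rep_ <- compare_two_groups(tbl, group2 = "asd_no_adhd")
  expect_setequal(rep_$feature, c("low_in_asd", "high_in_asd", "null_feat"))
  expect_gt(rep_$cohen_d[rep_$feature == "low_in_asd"], 0)
  expect_lt(rep_$cohen_d[rep_$feature == "high_in_asd"], 0)
  expect_true(all(rep_$p_t >= 0 & rep_$p_t <= 1))
  expect_true(all(rep_$p_u >= 0 & rep_$p_u <= 1))
  expect_true(rep_$bh_significant[rep_$feature == "high_in_asd"])

  # constant-in-both features are skipped, not fatal
  tbl$flat <- 1
  rep2 <- suppressMessages(compare_two_groups(tbl, group2 = "asd_no_adhd"))
  expect_true(is.na(rep2$p_t[rep2$feature == "flat"]))

  expect_error(compare_two_groups(tbl[tbl$group == "typical", ]),
               "both groups")
})

test_that("the U test is invariant under strictly monotone transforms", {
  set.seed(54)
  tbl <- tibble::tibble(group = rep(c("typical", "asd_adhd"), each = 12),
                        f = c(rnorm(12, 0.3), rnorm(12, 0)))
  r1 <- compare_two_groups(tbl, group2 = "asd_adhd")
  tbl$f <- exp(5 * tbl$f)
  r2 <- compare_two_groups(tbl, group2 = "asd_adhd")
  expect_equal(r1$p_u, r2$p_u, tolerance = 1e-12)
  expect_equal(r1$u, r2$u)
})

test_that("adjustment-coefficient comparisons pool cells as documented", {
  set.seed(55)
  types <- c("go_pos", "go_neg", "nogo_pos", "nogo_neg")
  fits <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:12),
    response_type = types, rep = 1:3
  )
  fits$group <- ifelse(as.integer(substring(fits$subject_id, 2)) <= 6,
                       "typical", "asd_no_adhd")
  shift <- ifelse(fits$group == "typical", 0.1, 0)
  fits$alpha <- rnorm(nrow(fits), 0.1 + shift, 0.02)
  fits$theta1 <- rnorm(nrow(fits), 0.6, 0.05)
  fits$theta2 <- rnorm(nrow(fits), 0.2, 0.05)
  fits$aic <- -5; fits$n <- 20; fits$y0 <- 0.5

  mixed <- compare_adjustment_groups(fits, group2 = "asd_no_adhd",
                                     mode = "mixed")
  expect_equal(nrow(mixed), 3)  # alpha, theta1, theta2
  expect_lt(mixed$p_t[mixed$feature == "alpha"], 0.01)

  split <- compare_adjustment_groups(fits, group2 = "asd_no_adhd",
                                     mode = "by_response_type")
  expect_equal(nrow(split), 12)  # 4 cells x 3 coefficients
  expect_setequal(unique(split$cell), types)
})
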
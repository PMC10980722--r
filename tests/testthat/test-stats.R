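test_that("HWE chi-square matches closed forms", {
  res <- hwe_test(c(25, 50, 25))
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  expect_equal(hwe_test(c(81, 18, 1))$chisq, 0)
  # D = p*q with no heterozygotes: chi-square = n
  expect_equal(hwe_test(c(50, 0, 50))$chisq, 100)
  expect_error(hwe_test(c(0, 0, 0)), "all-zero")
  expect_error(hwe_test(c(1, 2)), "3 counts")
})

test_that("bonferroni is the capped multiple", {
  expect_equal(bonferroni(0.005, 3), 0.015)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(1.5, 2), "0, 1")
  # monotone in both arguments, capped at 1
  ps <- seq(0, 1, by = 0.1)
  expect_true(all(diff(bonferroni(ps, 4)) >= 0))
  expect_true(all(bonferroni(0.3, 1:10) == pmin(1, 0.3 * 1:10)))
})

test_that("pearson_test matches the t-distribution oracle", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_test(c(1, 2, 3, 4), c(1, -1, -1, 1))$r, 0)
  set.seed(31)
  x <- rnorm(229); y <- 0.5 * x + rnorm(229) * sqrt(0.75)
  res <- pearson_test(x, y)
  r <- res$r; n <- 229
  p_oracle <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_test(1:2, 1:2), "length")
})

test_that("rm_anova matches hand computation and the aov oracle", {
  # 3 x 3 toy table, sums of squares by hand
  d <- matrix(c(1, 2, 3,
                2, 4, 6,
                3, 6, 9), nrow = 3, byrow = TRUE)
  res <- rm_anova(d)
  grand <- mean(d)
  ss_cond <- 3 * sum((colMeans(d) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(d) - grand)^2)
  ss_err <- sum((d - grand)^2) - ss_cond - ss_subj
  F_hand <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_equal(res$eta_sq_partial, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-10)
  expect_equal(res$df, c(2, 4))
  # conservation of total SS
  expect_equal(res$ss_total,
               res$ss_subject + res$ss_condition + res$ss_error,
               tolerance = 1e-10)
  # identical condition means: F = 0, eta = 0
  d0 <- matrix(rnorm(6), 6, 1)[, c(1, 1, 1)]
  res0 <- rm_anova(d0)
  expect_equal(res0$F, 0)
  expect_equal(res0$eta_sq_partial, 0)
  # random table vs the aov oracle
  set.seed(32)
  d2 <- matrix(rnorm(12 * 5), 12, 5)
  res2 <- rm_anova(d2)
  long <- data.frame(y = as.vector(d2), s = factor(rep(1:12, 5)),
                     cond = factor(rep(1:5, each = 12)))
  av <- summary(aov(y ~ cond + Error(s / cond), long))
  expect_equal(res2$F,
               av[["Error: s:cond"]][[1]]["cond", "F value"],
               tolerance = 1e-8)
  expect_equal(res2$p,
               av[["Error: s:cond"]][[1]]["cond", "Pr(>F)"],
               tolerance = 1e-8)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("post-hoc pairwise tests are paired t with m = C(c,2)", {
  set.seed(33)
  d <- matrix(rnorm(10 * 5), 10, 5)
  ph <- posthoc_bonferroni(d)
  expect_equal(nrow(ph), 10)                  # C(5, 2)
  tt <- t.test(d[, 1] - d[, 2])
  expect_equal(ph$t[1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ph$p_corrected[1], min(1, 10 * tt$p.value),
               tolerance = 1e-10)
  same <- posthoc_bonferroni(d[, c(1, 1)])
  expect_equal(same$t, 0)
  expect_equal(same$p_corrected, 1)
})

test_that("power computations match simulation and null limits", {
  # null limit: power equals alpha
  expect_equal(power_t_test2(100, 100, d = 0, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  expect_equal(power_correlation(200, r = 0, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  # d = 0.5 with groups 131/124 vs a Monte-Carlo oracle
  p_analytic <- power_t_test2(131, 124, d = 0.5, alpha = 0.05)
  set.seed(34)
  rej <- replicate(4000, {
    a <- rnorm(131, 0.5); b <- rnorm(124, 0)
    t.test(a, b, var.equal = TRUE)$p.value < 0.05
  })
  expect_lt(abs(p_analytic - mean(rej)),
            3 * sqrt(mean(rej) * (1 - mean(rej)) / 4000) + 0.005)
  # monotone in n and effect size
  expect_gt(power_t_test2(200, 200, 0.5), power_t_test2(50, 50, 0.5))
  expect_gt(power_correlation(300, 0.3), power_correlation(100, 0.3))
  expect_gt(power_correlation(100, 0.5), power_correlation(100, 0.3))
  expect_error(min_power(255, alpha = 2), "alpha")
})
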
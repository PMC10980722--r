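test_that("sphere offsets match exhaustive lattice enumeration", {
  for (r in 0:3) {
    off <- sphere_offsets(r)
    # independent brute force over a generous cube
    pts <- expand.grid(-5:5, -5:5, -5:5)
    pts <- pts[rowSums(pts^2) <= r^2, ]
    expect_equal(nrow(off), nrow(pts))
    expect_setequal(paste(off[, 1], off[, 2], off[, 3]),
                    paste(pts[, 1], pts[, 2], pts[, 3]))
    # symmetric under negation
    expect_setequal(paste(off[, 1], off[, 2], off[, 3]),
                    paste(-off[, 1], -off[, 2], -off[, 3]))
  }
  expect_equal(vapply(0:3, function(r) nrow(sphere_offsets(r)), 1L),
               c(1L, 7L, 33L, 123L))
  expect_error(sphere_offsets(-1), "nonnegative")
})

test_that("k-fold partitions are balanced and cover all subjects", {
  f <- kfold_partition(229, 10, seed = 4)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(rep(23L, 9), 22L))
  expect_setequal(unique(f), 1:10)
  f2 <- kfold_partition(7, 7, seed = 1)
  expect_true(all(table(f2) == 1))
  expect_error(kfold_partition(5, 6), "k <= n")
  for (s in 1:5) {
    fr <- kfold_partition(53, 4, seed = s)
    expect_equal(length(fr), 53)
    expect_true(max(table(fr)) - min(table(fr)) <= 1)
  }
})

test_that("SVR agrees with the quadratic-programming oracle", {
  skip_if_not_installed("kernlab")
  set.seed(5)
  for (rep in 1:3) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    y <- X %*% c(2, -1, 0.5) + rnorm(20, 0, 0.1)
    Xte <- matrix(rnorm(5 * 3), 5, 3)
    expect_equal(svr_train_predict(X, y, Xte),
                 svr_qp_oracle(X, y, Xte), tolerance = 0.02)
  }
  # y = 2x: prediction at x = 5 within 0.05 of 10
  x <- matrix(seq(0, 4.75, by = 0.25), ncol = 1)
  p <- svr_train_predict(x, 2 * drop(x), matrix(5), C = 100,
                         epsilon = 0.01)
  expect_lt(abs(p - 10), 0.05)
})

test_that("SVR handles degenerate and duplicated inputs", {
  set.seed(6)
  X <- matrix(rnorm(12), 6, 2)
  expect_equal(svr_train_predict(X, rep(3, 6), X), rep(3, 6))
  expect_error(svr_train_predict(X[0, , drop = FALSE], numeric(0), X),
               "empty")
  expect_error(svr_train_predict(X, rnorm(6), X[, 1, drop = FALSE]),
               "feature counts")
  expect_error(svr_train_predict(X * NA, rnorm(6), X), "finite")
  # duplicated column == single column scaled sqrt(2) (linear-kernel identity)
  x1 <- matrix(rnorm(15), ncol = 1)
  y <- 1.5 * drop(x1) + rnorm(15, 0, 0.2)
  xte <- matrix(rnorm(4), ncol = 1)
  p_dup <- svr_train_predict(cbind(x1, x1), y, cbind(xte, xte))
  p_scaled <- svr_train_predict(x1 * sqrt(2), y, xte * sqrt(2))
  expect_equal(p_dup, p_scaled, tolerance = 1e-6)
  skip_if_not_installed("kernlab")
  expect_equal(p_dup, svr_qp_oracle(cbind(x1, x1), y, cbind(xte, xte)),
               tolerance = 0.02)
})

test_that("BH thresholding matches the literal step-up definition", {
  p4 <- c(0.001, 0.008, 0.039, 0.041)
  res <- fdr_threshold(p4, 0.05)
  expect_true(all(res$significant))         # k* = 4: 0.041 <= 4/4 * 0.05
  expect_equal(res$critical_p, 0.041)
  expect_false(any(fdr_threshold(rep(1, 10), 0.05)$significant))
  set.seed(7)
  for (rep in 1:200) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_threshold(p, q)$significant, bh_stepup(p, q))
  }
  expect_error(fdr_threshold(numeric(0), 0.05), "empty")
  expect_error(fdr_threshold(c(0.5, 1.5), 0.05), "0, 1")
  expect_error(fdr_threshold(0.5, 1.2), "0, 1")
})

test_that("the family FDR budget over 4 contrasts gives q = 0.0125", {
  expect_identical(per_map_q(0.05, 4), 0.0125)
})

test_that("radius-0 searchlight equals per-voxel single-feature CV", {
  sp <- tiny_pattern_spec(n = 12, strength = 0.5)
  co <- simulate_cohort(sp)
  maps <- fit_first_level(co)
  y <- co$phenotypes$asq_total
  sl <- searchlight_predict(
    maps, y, searchlight_spec(radius_vox = 0, n_folds = 4, min_voxels = 1,
                              cv_seed = 9))
  folds <- kfold_partition(12, 4, 9)
  for (v in c(3, 40, 77)) {
    expect_equal(sl$r[v],
                 manual_cv_r(unclass(maps)[, v, drop = FALSE], y, folds, 4))
  }
})

test_that("searchlight rejects degenerate targets and tiny cohorts", {
  sp <- tiny_pattern_spec(n = 6)
  co <- simulate_cohort(sp)
  maps <- fit_first_level(co)
  expect_error(searchlight_predict(maps, rep(20, 6)), "degenerate target")
  expect_error(searchlight_predict(maps, 1:6,
                                   searchlight_spec(n_folds = 10)),
               "fewer subjects")
})

test_that("searchlight recovers an injected pattern region", {
  sp <- tiny_pattern_spec(n = 24, noise_sd = 0.3, strength = 0.6, seed = 13)
  co <- simulate_cohort(sp)
  maps <- fit_first_level(co)
  sl <- searchlight_predict(
    maps, co$phenotypes$asq_total,
    searchlight_spec(radius_vox = 2, n_folds = 6, min_voxels = 5,
                     cv_seed = 2))
  inreg <- sl$voxel %in% sp$pattern_region
  expect_gt(median(sl$r[inreg]), median(sl$r[!inreg]))
  expect_true(all(sl$r >= -1 & sl$r <= 1, na.rm = TRUE))
  expect_true(all(sl$p > 0 & sl$p <= 1, na.rm = TRUE))
  expect_true(all(sl$fdr_sig[is.na(sl$r)] == FALSE))
})

test_that("permutation p-values broadly agree with parametric ones", {
  g <- tiny_grid(c(6, 6, 6), mask_radius = 2.2)
  sp <- cohort_spec(n_subjects = 12, grid = g, volumes_per_run = 160,
                    noise_sd = 0.5,
                    pattern_region = voxel_ball(g, c(3, 3, 3), 1),
                    pattern_strength = 0.5, rng_seed = 3)
  co <- simulate_cohort(sp)
  maps <- fit_first_level(co)
  y <- co$phenotypes$asq_total
  base <- searchlight_spec(radius_vox = 1, n_folds = 4, min_voxels = 1,
                           cv_seed = 5)
  sl_t <- searchlight_predict(maps, y, base)
  base$p_method <- "permutation"; base$n_perm <- 59L
  sl_p <- searchlight_predict(maps, y, base)
  expect_true(all(sl_p$p >= 1 / 60 & sl_p$p <= 1))
  expect_identical(sl_p$r, sl_t$r)
})
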
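test_that("ASQ scoring is the item sum with range 0-50", {
  expect_identical(asq_total(rep(1L, 50)), 50L)
  expect_identical(asq_total(rep(0L, 50)), 0L)
  expect_error(asq_total(rep(1, 49)), "50 items")
  ph <- simulate_asq_responses(40, seed = 1)
  expect_identical(ph$asq_total,
                   vapply(ph$items, function(x) sum(x), 1L))
  expect_true(all(ph$asq_total >= 0 & ph$asq_total <= 50))
})

test_that("ASQ totals match the target population mean and SD", {
  ph <- simulate_asq_responses(2000, seed = 11)
  expect_lt(abs(mean(ph$asq_total) - 21.4), 0.1 * 21.4)
  expect_lt(abs(sd(ph$asq_total) - 5.6), 0.1 * 5.6)
  expect_error(simulate_asq_responses(0), "positive")
  expect_error(simulate_asq_responses(5, c(21.4, -1)), "nonneg")
})

test_that("higher latent traits give higher expected totals", {
  par <- traitscan:::asq_item_parameters(21.4, 5.6)
  draw_total <- function(z, reps, seed) {
    withr::with_seed(seed, {
      p <- stats::plogis(par$discrimination * (z - par$difficulty))
      colSums(matrix(stats::rbinom(50 * reps, 1, rep(p, reps)), nrow = 50))
    })
  }
  lo <- draw_total(-2, 10000, 1)
  hi <- draw_total(2, 10000, 2)
  expect_gt(mean(hi), mean(lo))
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  gt <- simulate_genotypes(10000, allele_freqs = c(rs2254298 = 0.5),
                           seed = 2)
  het <- mean(gt$genotype_rs2254298 == "AG")
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 10000) + 0.005)
  # degenerate frequency: everyone homozygous for the risk allele
  gt1 <- simulate_genotypes(50, allele_freqs = c(rs2254298 = 1), seed = 3)
  expect_true(all(gt1$genotype_rs2254298 == "AA"))
  expect_true(all(gt1$carrier_rs2254298 == 1))
  expect_error(simulate_genotypes(10, allele_freqs = c(rs2254298 = 0)),
               "frequencies")
  # carrier flag consistent with genotype
  gt2 <- simulate_genotypes(500, seed = 4)
  expect_identical(gt2$carrier_rs2268491,
                   as.integer(grepl("T", gt2$genotype_rs2268491)))
})

test_that("simulated genotypes pass the HWE test at the nominal rate", {
  rejections <- vapply(1:400, function(s) {
    gt <- simulate_genotypes(229, allele_freqs = c(rs2254298 = 0.3),
                             seed = 1000 + s)
    cnt <- genotype_counts(gt$genotype_rs2254298, "A")
    hwe_test(cnt)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("event schedules have the paradigm's structure", {
  sp <- cohort_spec(n_subjects = 2)
  ev <- build_event_schedule(sp, seed = 1)
  expect_equal(nrow(ev), 100)
  counts <- dplyr::count(ev, condition)
  expect_true(all(counts$n == 20))
  per_run <- dplyr::count(ev, run, condition)
  expect_true(all(per_run$n == 10))
  # every stimulus exactly once per run
  expect_true(all(table(ev$stimulus_id, ev$run) == 1))
  # strictly increasing onsets within run, different order across runs
  for (r in 1:2) {
    on <- ev$onset[ev$run == r]
    expect_true(all(diff(on) > 0))
  }
  expect_false(identical(ev$stimulus_id[ev$run == 1],
                         ev$stimulus_id[ev$run == 2]))
  # determinism
  expect_identical(ev, build_event_schedule(sp, seed = 1))
  # run too short
  sp_short <- cohort_spec(n_subjects = 2, volumes_per_run = 60)
  expect_error(build_event_schedule(sp_short, seed = 1), "too short")
})

test_that("cohort simulation is deterministic and conserves structure", {
  sp <- tiny_pattern_spec(n = 3)
  co1 <- simulate_cohort(sp)
  co2 <- simulate_cohort(sp)
  expect_identical(co1$phenotypes, co2$phenotypes)
  expect_identical(simulate_subject_bold(co1, 2)$bold,
                   simulate_subject_bold(co2, 2)$bold)
  # genotype counts sum to n
  cnt <- genotype_counts(co1$phenotypes$genotype_rs53576, "A")
  expect_equal(sum(cnt), 3)
})

test_that("region constraints are enforced", {
  g <- tiny_grid()
  ball <- voxel_ball(g, c(5, 5, 5), 1)
  expect_error(
    cohort_spec(grid = g, pattern_region = ball,
                coupling_seed_region = ball,
                coupling_slopes = c(carrier = 0, noncarrier = 0)),
    "disjoint")
  expect_error(cohort_spec(grid = g, pattern_region = prod(g$dim) + 5L),
               "outside the grid")
})

test_that("noiseless cohorts yield exactly recoverable amplitudes", {
  sp <- tiny_pattern_spec(n = 2, noise_sd = 0, strength = 0.4)
  co <- simulate_cohort(sp)
  sub <- simulate_subject_bold(co, 1)
  X <- build_design_matrix(co$schedule, sp$volumes_per_run, co$hrf,
                           motion = sub$motion)
  fit <- fit_glm(sub$bold, X, sp$grid)
  cm <- contrast_map(fit, contrast_weights(X))
  pat_cols <- traitscan:::mask_columns(sp$grid, sp$pattern_region)
  expect_equal(unname(cm[pat_cols]),
               unname(co$ground_truth$pattern_amplitudes[1, ]),
               tolerance = 1e-8)
  off <- setdiff(seq_along(cm), pat_cols)
  expect_lt(max(abs(cm[off])), 1e-8)
})

test_that("trait-amplitude calibration hits its target at n = 200", {
  g <- tiny_grid(c(12, 12, 12), mask_radius = 4)
  pat <- voxel_ball(g, c(6, 6, 6), 2)
  base <- cohort_spec(n_subjects = 200, grid = g, volumes_per_run = 160,
                      noise_sd = 0.5, pattern_region = pat,
                      pattern_strength = 1, rng_seed = 17)
  s <- calibrate_pattern_strength(base, 0.5)
  sp <- cohort_spec(n_subjects = 200, grid = g, volumes_per_run = 160,
                    noise_sd = 0.5, pattern_region = pat,
                    pattern_strength = s, rng_seed = 17)
  co <- simulate_cohort(sp)
  maps <- fit_first_level(co)
  pat_cols <- traitscan:::mask_columns(g, pat)
  r <- cor(rowMeans(unclass(maps)[, pat_cols]), co$phenotypes$asq_total)
  expect_lt(abs(r - 0.5), 0.1)
})

test_that("behavior simulator respects supports and null effects", {
  ph <- simulate_phenotypes(300, seed = 1)
  null_spec <- list(accuracy_offsets = numeric(), rt_offsets_s = numeric())
  bh <- simulate_behavior(ph, null_spec, seed = 2)
  expect_true(all(bh$accuracy >= 0 & bh$accuracy <= 1))
  expect_true(all(bh$rt_s > 0))
  means <- tapply(bh$accuracy, bh$condition, mean)
  expect_lt(diff(range(means)), 0.02)
  expect_error(
    simulate_behavior(ph, list(accuracy_offsets = c(angry = 0.2)),
                      seed = 1),
    "\\[0, 1\\]")
})

test_that("negative-emotion accuracy decrement is detectable by RM-ANOVA", {
  hits <- vapply(1:40, function(s) {
    ph <- tibble::tibble(subject_id = sprintf("s%03d", 1:200))
    bh <- simulate_behavior(ph, seed = 3000 + s)
    wide <- tidyr::pivot_wider(bh[c("subject_id", "condition", "accuracy")],
                               names_from = "condition",
                               values_from = "accuracy")
    rm_anova(wide[-1])$p < 0.01
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
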
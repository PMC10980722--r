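#' Simulate a synthetic cohort
#'
#' Draws everything that defines a cohort except the scan noise: phenotypes
#' (ASQ, genotypes, demographics), the event schedule, the per-voxel pattern
#' weights of the trait-encoding region, per-subject amplitude deviations,
#' and per-subject condition-specific seed-to-target coupling gains. BOLD
#' volumes are generated per subject by [simulate_subject_bold()] so large
#' cohorts never need all volumes in memory at once; everything is
#' deterministic given `spec$rng_seed`.
#'
#' The injected structure is: every in-mask voxel responds to all five
#' conditions with unit amplitude; inside `pattern_region` the
#' (angry - neutral) amplitude of voxel v for subject i is
#' `w_v * pattern_strength * z_i + e_vi` with `z_i` the standardized trait,
#' `w_v` the stored pattern weight and `e_vi` amplitude noise; seed-region
#' voxels follow a shared trial-jittered neural series; target-region voxels
#' additionally receive `gain_ci x` (seed neural series restricted to
#' condition c), with the angry-condition gain
#' `coupling_base + slope(genotype group) * z_i`.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `spec`, `phenotypes`, `schedule`,
#'   `ground_truth` (pattern weights, per-subject amplitudes and coupling
#'   gains, group slopes), and `hrf`.
#' @export
#' @examples
#' sp <- cohort_spec(n_subjects = 3, grid = volume_grid(c(8, 8, 8)),
#'                   volumes_per_run = 160)
#' co <- simulate_cohort(sp)
#' co$ground_truth$coupling_gains
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  phenotypes <- simulate_phenotypes(spec$n_subjects,
                                    c(spec$asq_mean, spec$asq_sd),
                                    seed = spec$rng_seed)
  schedule <- build_event_schedule(spec, seed = spec$rng_seed + 10L)
  gt <- make_ground_truth(phenotypes, spec)
  structure(list(spec = spec, phenotypes = phenotypes, schedule = schedule,
                 ground_truth = gt, hrf = hrf_model(tr_s = spec$tr_s)),
            class = "synthetic_cohort")
}

make_ground_truth <- function(phenotypes, spec) {
  n <- nrow(phenotypes)
  z <- as.numeric(scale(phenotypes$asq_total))
  if (any(!is.finite(z))) z <- rep(0, n)   # degenerate constant trait
  npat <- length(spec$pattern_region)
  weights <- withr::with_seed(spec$rng_seed + 20L,
                              stats::rnorm(npat, mean = 1, sd = 0.2))
  amp_noise <- withr::with_seed(
    spec$rng_seed + 30L,
    matrix(stats::rnorm(n * npat, 0, spec$amp_noise_sd), n, npat))
  subject_amp <- withr::with_seed(
    spec$rng_seed + 31L, stats::rnorm(n, 0, spec$subject_amp_sd))
  pattern_amp <- if (npat)
    outer(spec$pattern_strength * z + subject_amp, weights) + amp_noise else
      matrix(0, n, 0)
  carrier_col <- paste0("carrier_", spec$coupling_snp)
  carrier <- if (carrier_col %in% names(phenotypes))
    phenotypes[[carrier_col]] else rep(0L, n)
  slope <- ifelse(carrier == 1, spec$coupling_slopes$carrier,
                  spec$coupling_slopes$noncarrier)
  gains <- tibble::tibble(
    subject_id = phenotypes$subject_id,
    carrier = carrier,
    trait_z = z,
    gain_angry = spec$coupling_base + slope * z,
    gain_fear = 0, gain_happy = 0, gain_neutral = 0, gain_sad = 0
  )
  list(trait_z = z,
       subject_amp = subject_amp,
       pattern_voxels = spec$pattern_region,
       pattern_weights = weights,
       pattern_amplitudes = pattern_amp,   # subjects x pattern voxels
       coupling_gains = gains,
       group_slopes = spec$coupling_slopes)
}

subject_seed <- function(spec, i) {
  as.integer((abs(spec$rng_seed) * 131L + i) %% .Machine$integer.max)
}

#' Simulate one subject's BOLD data
#'
#' Generates the runs-stacked scans-by-voxels BOLD matrix (in-mask voxels of
#' the cohort grid) for one subject: baseline 100 + HRF-convolved condition
#' responses + injected pattern/coupling signal + motion contribution +
#' i.i.d. Gaussian scan noise of SD `spec$noise_sd`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param i Subject index.
#' @return List with `bold` (`(volumes_per_run * n_runs) x n_voxels`
#'   matrix), `motion` (scans x 6), and `seed_neural` (the fine-grid neural
#'   series of the seed region per run, for reference).
#' @export
simulate_subject_bold <- function(cohort, i) {
  spec <- cohort$spec
  grid <- spec$grid
  hrf <- cohort$hrf
  n_scans <- spec$volumes_per_run
  V <- sum(grid$mask)
  conds <- emotion_conditions()
  gt <- cohort$ground_truth
  gains <- unlist(gt$coupling_gains[i, paste0("gain_", conds)])
  pat_cols <- mask_columns(grid, spec$pattern_region)
  seed_cols <- mask_columns(grid, spec$coupling_seed_region)
  targ_cols <- mask_columns(grid, spec$coupling_target_region)

  withr::local_seed(subject_seed(spec, i))
  bold <- matrix(0, n_scans * spec$n_runs, V)
  motion <- matrix(0, n_scans * spec$n_runs, 6)
  seed_neural <- vector("list", spec$n_runs)
  mot_coef <- stats::rnorm(6, 0, 0.2)
  for (r in seq_len(spec$n_runs)) {
    ev <- cohort$schedule[cohort$schedule$run == r, , drop = FALSE]
    rows <- (r - 1) * n_scans + seq_len(n_scans)
    # unit condition regressors (shared shape across voxels)
    C <- convolve_conditions(transform(ev, duration = 0), n_scans, hrf,
                             conds)
    # trial-jittered regressors: per-event gain 1 + eta
    eta <- stats::rnorm(nrow(ev), 0, spec$trial_gain_sd)
    J <- convolve_jittered(ev, n_scans, hrf, conds, 1 + eta)
    seed_neural[[r]] <- attr(J, "neural")
    # amplitude matrix: every voxel responds to every condition with amp 1
    sig <- matrix(rowSums(C), n_scans, V)
    if (length(pat_cols))
      sig[, pat_cols] <- sig[, pat_cols] +
        C[, "angry"] %o% gt$pattern_amplitudes[i, ]
    if (length(seed_cols))
      sig[, seed_cols] <- matrix(rowSums(J), n_scans, length(seed_cols))
    if (length(targ_cols))
      sig[, targ_cols] <- sig[, targ_cols] +
        matrix(J %*% gains, n_scans, length(targ_cols))
    mot <- apply(matrix(stats::rnorm(n_scans * 6, 0, 0.02), n_scans, 6),
                 2, cumsum)
    motion[rows, ] <- mot
    bold[rows, ] <- 100 + sig + drop(mot %*% mot_coef)
  }
  if (spec$noise_sd > 0)
    bold <- bold + stats::rnorm(length(bold), 0, spec$noise_sd)
  list(bold = bold, motion = motion, seed_neural = seed_neural)
}

# per-condition regressors with per-event amplitudes; also returns the
# underlying fine-grid neural series (sum over conditions) as an attribute
convolve_jittered <- function(ev, n_scans, hrf, conds, amps) {
  dt <- hrf$tr_s / hrf$oversampling
  n_fine <- n_scans * hrf$oversampling
  kern <- canonical_hrf(hrf)
  scan_idx <- 1L + (seq_len(n_scans) - 1L) * hrf$oversampling
  out <- matrix(0, n_scans, length(conds), dimnames = list(NULL, conds))
  neural <- numeric(n_fine)
  for (ci in seq_along(conds)) {
    rows <- which(ev$condition == conds[ci])
    if (!length(rows)) next
    stick <- numeric(n_fine)
    idx <- 1L + floor(ev$onset[rows] / dt)
    stick[idx] <- amps[rows]
    neural <- neural + stick
    conv <- stats::convolve(stick, rev(kern), type = "open")[seq_len(n_fine)]
    out[, ci] <- conv[scan_idx]
  }
  attr(out, "neural") <- neural
  out
}

#' Simulate BOLD volumes for a whole cohort
#'
#' Materializes every subject's BOLD matrix at once (suitable for small
#' cohorts; pipelines over large cohorts should iterate
#' [simulate_subject_bold()] instead).
#'
#' @param phenotypes Phenotype tibble (as from [simulate_phenotypes()]).
#' @param schedule Event tibble (as from [build_event_schedule()]).
#' @param spec A [cohort_spec()]; `spec$n_subjects` must equal
#'   `nrow(phenotypes)`.
#' @return List with `bold` (list of scans x voxels matrices), `motion`
#'   (list of scans x 6 matrices), and `ground_truth`.
#' @export
simulate_cohort_bold <- function(phenotypes, schedule, spec) {
  stopifnot(inherits(spec, "cohort_spec"),
            nrow(phenotypes) == spec$n_subjects)
  cohort <- structure(
    list(spec = spec, phenotypes = phenotypes, schedule = schedule,
         ground_truth = make_ground_truth(phenotypes, spec),
         hrf = hrf_model(tr_s = spec$tr_s)),
    class = "synthetic_cohort")
  subs <- lapply(seq_len(spec$n_subjects),
                 function(i) simulate_subject_bold(cohort, i))
  list(bold = lapply(subs, `[[`, "bold"),
       motion = lapply(subs, `[[`, "motion"),
       ground_truth = cohort$ground_truth)
}

#' First-level contrast maps for a synthetic cohort
#'
#' Runs the first-level GLM (joint fit across runs, run-specific condition,
#' motion and intercept columns) for every subject and assembles the
#' requested contrast into a subjects-by-voxels matrix.
#'
#' @param cohort A `synthetic_cohort`.
#' @param plus,minus Conditions contrasted (default angry > neutral).
#' @return A `contrast_maps` object: subjects x in-mask-voxels matrix with
#'   attributes `grid`, `subject_id`, `contrast`.
#' @export
fit_first_level <- function(cohort, plus = "angry", minus = "neutral") {
  spec <- cohort$spec
  n <- spec$n_subjects
  maps <- NULL
  for (i in seq_len(n)) {
    sub <- simulate_subject_bold(cohort, i)
    X <- build_design_matrix(cohort$schedule, spec$volumes_per_run,
                             cohort$hrf, motion = sub$motion)
    fit <- fit_glm(sub$bold, X, spec$grid)
    cm <- contrast_map(fit, contrast_weights(X, plus, minus))
    if (is.null(maps)) maps <- matrix(0, n, length(cm))
    maps[i, ] <- cm
  }
  contrast_maps(maps, spec$grid, cohort$phenotypes$subject_id,
                paste0(plus, ">", minus))
}

#' Construct a contrast-map collection
#'
#' @param maps Subjects x in-mask-voxels matrix of contrast values.
#' @param grid The shared [volume_grid()].
#' @param subject_id Subject identifiers.
#' @param contrast Contrast label.
#' @return A `contrast_maps` object.
#' @export
contrast_maps <- function(maps, grid, subject_id = NULL,
                          contrast = "angry>neutral") {
  stopifnot(is.matrix(maps), ncol(maps) == sum(grid$mask))
  structure(maps, grid = grid, contrast = contrast,
            subject_id = subject_id %||% sprintf("sub-%03d",
                                                 seq_len(nrow(maps))),
            class = c("contrast_maps", "matrix", "array"))
}

#' Calibrate the pattern strength for a target trait correlation
#'
#' Uses the generator's closed-form signal model to choose
#' `pattern_strength` so that the Pearson correlation between the trait and
#' the mean (angry - neutral) contrast estimate over `pattern_region` equals
#' `target_r`: with mean pattern weight `w`, region size `m`, subject-level
#' amplitude SD `su`, voxel amplitude noise `sa` and GLM contrast noise `sg`
#' (from the design efficiency),
#' `r = s*w / sqrt(s^2 w^2 + su^2 w^2 + (sa^2 + sg^2) / m)`.
#'
#' @param spec A [cohort_spec()] with a nonempty `pattern_region`.
#' @param target_r Desired trait-contrast correlation in (0, 1).
#' @return The calibrated `pattern_strength` (scalar).
#' @export
calibrate_pattern_strength <- function(spec, target_r = 0.5) {
  stopifnot(length(spec$pattern_region) > 0, target_r > 0, target_r < 1)
  m <- length(spec$pattern_region)
  sg2 <- glm_contrast_variance(spec)
  noise <- spec$subject_amp_sd^2 + (spec$amp_noise_sd^2 + sg2) / m
  w <- 1  # mean pattern weight by construction
  sqrt(target_r^2 * noise / (1 - target_r^2)) / w
}

# variance of the angry-neutral contrast estimate under the cohort design
glm_contrast_variance <- function(spec) {
  hrf <- hrf_model(tr_s = spec$tr_s)
  sched <- build_event_schedule(spec, seed = spec$rng_seed + 10L)
  X <- build_design_matrix(sched, spec$volumes_per_run, hrf,
                           motion = matrix(0, spec$volumes_per_run *
                                             spec$n_runs, 6))
  keep <- !grepl("_mot", colnames(X))
  X <- X[, keep, drop = FALSE]
  w <- contrast_weights(X)
  spec$noise_sd^2 * drop(t(w) %*% solve(crossprod(X), w))
}
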
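#' Preset study conditions for the synthetic experiments
#'
#' Three frozen cohort presets used by the package's validation experiments,
#' all on a 16x16x16 desk-scale grid at 3 mm:
#'
#' * `null_cohort_spec()` — no injected signal anywhere (type-I error
#'   studies); spherical mask of radius 4 voxels (257 voxels).
#' * `pattern_cohort_spec()` — a radius-3 lattice ball (123 voxels) at the
#'   mask centre carries a trait-encoding (angry - neutral) pattern whose
#'   strength is calibrated so the region-mean amplitude correlates
#'   `target_r` with the trait; the default `target_r = 0.9` is chosen so
#'   that the fold-level searchlight test has adequate detection power at
#'   the desk-scale cohort size (n = 60) under the stringent q = 0.0125
#'   FDR threshold; mask radius 6 (912 voxels).
#' * `coupling_cohort_spec()` — disjoint radius-2 seed and target balls
#'   (33 voxels each); the angry-condition seed-to-target coupling gain has
#'   opposite trait slopes in the two carrier groups of `snp`; mask radius
#'   5.2 (624 voxels).
#'
#' @param n_subjects Cohort size (default 60).
#' @param seed Cohort RNG seed.
#' @param target_r Calibration target for the trait vs region-mean
#'   (angry - neutral) amplitude correlation.
#' @param slope Magnitude of the per-group coupling slope (carrier
#'   `-slope`, non-carrier `+slope`, per SD of trait).
#' @param snp SNP whose carrier status moderates the coupling.
#' @return A [cohort_spec()].
#' @name cohort_presets
NULL

#' @rdname cohort_presets
#' @export
null_cohort_spec <- function(n_subjects = 60, seed = 1L) {
  cohort_spec(
    n_subjects = n_subjects,
    grid = default_grid(c(16, 16, 16), mask_radius_vox = 4),
    noise_sd = 1, rng_seed = seed
  )
}

#' @rdname cohort_presets
#' @export
pattern_cohort_spec <- function(n_subjects = 60, seed = 1L,
                                target_r = 0.9) {
  grid <- default_grid(c(16, 16, 16), mask_radius_vox = 6)
  pat <- voxel_ball(grid, c(8, 8, 8), 3)
  base <- cohort_spec(
    n_subjects = n_subjects, grid = grid, noise_sd = 0.5,
    pattern_region = pat, pattern_strength = 1,
    amp_noise_sd = 0.05, subject_amp_sd = 0.02, rng_seed = seed
  )
  base$pattern_strength <- calibrate_pattern_strength(base, target_r)
  base
}

#' @rdname cohort_presets
#' @export
coupling_cohort_spec <- function(n_subjects = 60, seed = 1L, slope = 0.8,
                                 snp = "rs2254298") {
  grid <- default_grid(c(16, 16, 16), mask_radius_vox = 5.2)
  cohort_spec(
    n_subjects = n_subjects, grid = grid, noise_sd = 1,
    coupling_seed_region = voxel_ball(grid, c(6, 8, 8), 2),
    coupling_target_region = voxel_ball(grid, c(11, 8, 8), 2),
    coupling_slopes = c(carrier = -slope, noncarrier = slope),
    coupling_base = 0.3, coupling_snp = snp, trial_gain_sd = 1,
    rng_seed = seed
  )
}
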
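#' Specify a synthetic cohort
#'
#' Bundles every parameter of the synthetic fMRI cohort generator: sample
#' size, acquisition geometry and timing, noise level, the voxel region that
#' carries a trait-encoding multivariate pattern, and the seed/target regions
#' whose condition-specific coupling slope differs by genotype group.
#' Defaults reproduce the emulated study design: 2 runs of 173 volumes,
#' 5 face-emotion conditions, 50 events per run.
#'
#' @param n_subjects Number of subjects.
#' @param grid A [volume_grid()]; default a 20x20x20 lattice at 3 mm
#'   isotropic with an ellipsoidal grey-matter mask.
#' @param n_runs,volumes_per_run,tr_s Acquisition design (defaults 2, 173,
#'   2 s).
#' @param noise_sd Gaussian scan noise SD (BOLD units; baseline is 100).
#' @param pattern_region Linear voxel indices carrying the trait-encoding
#'   (angry - neutral) pattern.
#' @param pattern_strength Slope of the standardized trait on the
#'   (angry - neutral) amplitude in `pattern_region`; see
#'   [calibrate_pattern_strength()].
#' @param amp_noise_sd Subject-by-voxel amplitude noise SD inside
#'   `pattern_region`.
#' @param subject_amp_sd SD of the subject-level response-amplitude factor
#'   shared by all `pattern_region` voxels (trait-independent individual
#'   reactivity).
#' @param coupling_seed_region,coupling_target_region Linear voxel indices of
#'   the gPPI seed and target regions (disjoint from each other and from
#'   `pattern_region`).
#' @param coupling_slopes Named list/vector with elements `carrier` and
#'   `noncarrier`: slope of the standardized trait on the angry-condition
#'   seed-to-target coupling gain in each genotype group.
#' @param coupling_base Baseline angry-condition coupling gain common to both
#'   groups.
#' @param coupling_snp Which SNP's carrier status moderates the coupling.
#' @param event_duration_s,iti_range_s Stimulus duration and uniform
#'   inter-trial-interval jitter range (s).
#' @param trial_gain_sd SD of the per-event multiplicative amplitude jitter of
#'   the seed neural series (gives the PPI regressor trial-wise variance).
#' @param asq_mean,asq_sd Target population mean/SD of ASQ totals.
#' @param rng_seed Integer seed making the whole cohort reproducible.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 229,
                        grid = NULL,
                        n_runs = 2,
                        volumes_per_run = 173,
                        tr_s = 2,
                        noise_sd = 1,
                        pattern_region = integer(),
                        pattern_strength = 0,
                        amp_noise_sd = 0.05,
                        subject_amp_sd = 0.25,
                        coupling_seed_region = integer(),
                        coupling_target_region = integer(),
                        coupling_slopes = c(carrier = 0, noncarrier = 0),
                        coupling_base = 0,
                        coupling_snp = "rs2254298",
                        event_duration_s = 1,
                        iti_range_s = c(2, 6),
                        trial_gain_sd = 0.5,
                        asq_mean = 21.4,
                        asq_sd = 5.6,
                        rng_seed = 1L) {
  if (is.null(grid)) grid <- default_grid()
  stopifnot(inherits(grid, "volume_grid"),
            n_subjects >= 1, n_runs >= 1, volumes_per_run >= 1,
            tr_s > 0, noise_sd >= 0, amp_noise_sd >= 0,
            subject_amp_sd >= 0,
            length(iti_range_s) == 2, iti_range_s[1] > 0,
            iti_range_s[2] >= iti_range_s[1])
  nvox <- prod(grid$dim)
  regions <- list(pattern = pattern_region,
                  seed = coupling_seed_region,
                  target = coupling_target_region)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) && (any(r < 1) || any(r > nvox)))
      stop(sprintf("%s region outside the grid", nm))
    if (length(r) && !all(grid$mask[r]))
      stop(sprintf("%s region must lie inside the grey-matter mask", nm))
  }
  if (length(intersect(pattern_region, coupling_seed_region)) ||
      length(intersect(pattern_region, coupling_target_region)) ||
      length(intersect(coupling_seed_region, coupling_target_region)))
    stop("pattern, seed and target regions must be pairwise disjoint")
  cs <- as.list(coupling_slopes)
  if (!all(c("carrier", "noncarrier") %in% names(cs)))
    stop("coupling_slopes needs elements 'carrier' and 'noncarrier'")
  structure(
    list(n_subjects = as.integer(n_subjects), grid = grid,
         n_runs = as.integer(n_runs),
         volumes_per_run = as.integer(volumes_per_run), tr_s = tr_s,
         noise_sd = noise_sd, pattern_region = as.integer(pattern_region),
         pattern_strength = pattern_strength, amp_noise_sd = amp_noise_sd,
         subject_amp_sd = subject_amp_sd,
         coupling_seed_region = as.integer(coupling_seed_region),
         coupling_target_region = as.integer(coupling_target_region),
         coupling_slopes = cs, coupling_base = coupling_base,
         coupling_snp = coupling_snp,
         event_duration_s = event_duration_s, iti_range_s = iti_range_s,
         trial_gain_sd = trial_gain_sd,
         asq_mean = asq_mean, asq_sd = asq_sd,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, %d run(s) x %d volumes, TR %g s, noise SD %g\n",
    x$n_subjects, x$n_runs, x$volumes_per_run, x$tr_s, x$noise_sd))
  cat(sprintf("  pattern region: %d voxels (strength %g); seed/target: %d/%d voxels\n",
              length(x$pattern_region), x$pattern_strength,
              length(x$coupling_seed_region),
              length(x$coupling_target_region)))
  invisible(x)
}

# desk-scale stand-in for MNI space: 20^3 lattice, 3 mm isotropic,
# ellipsoidal grey-matter mask
default_grid <- function(dim = c(20, 20, 20), voxel_size_mm = 3,
                         mask_radius_vox = NULL) {
  dim <- as.integer(dim)
  if (is.null(mask_radius_vox)) mask_radius_vox <- (min(dim) - 2) / 2
  ctr <- (dim + 1) / 2
  ijk <- arrayInd(seq_len(prod(dim)), dim)
  d2 <- (ijk[, 1] - ctr[1])^2 + (ijk[, 2] - ctr[2])^2 + (ijk[, 3] - ctr[3])^2
  mask <- array(d2 <= mask_radius_vox^2, dim)
  volume_grid(dim, voxel_size_mm, mask = mask)
}

#' Face-emotion condition labels
#'
#' The five conditions of the implicit emotion-recognition paradigm, in the
#' fixed order used by every design matrix in the package.
#' @export
emotion_conditions <- function() c("angry", "fear", "happy", "neutral", "sad")
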
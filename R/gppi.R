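#' Define a gPPI seed
#'
#' @param name Seed label (e.g. `"ofc"`).
#' @param center_mm Sphere centre in mm coordinates.
#' @param radius_mm Sphere radius in mm (default 6, the conventional seed
#'   size).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mm, radius_mm = 6) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm), class = "seed_spec")
}

#' Extract a seed time series
#'
#' Mean BOLD series over all in-mask voxels whose mm centre lies within the
#' seed sphere (centre-in-sphere rule through the grid affine).
#'
#' @param bold Scans x in-mask-voxels matrix, or a 4-D array.
#' @param grid The [volume_grid()].
#' @param seed A [seed_spec()].
#' @return Numeric per-scan series.
#' @export
extract_seed_timeseries <- function(bold, grid, seed) {
  stopifnot(inherits(seed, "seed_spec"))
  vox <- mm_sphere(grid, seed$center_mm, seed$radius_mm)
  if (!length(vox)) stop("seed sphere does not intersect the mask")
  if (is.array(bold) && length(dim(bold)) == 4) {
    bold <- t(apply(bold, 4, function(v) v[grid$mask]))
    if (sum(grid$mask) == 1) bold <- t(bold)
  }
  cols <- mask_columns(grid, vox)
  rowMeans(bold[, cols, drop = FALSE])
}

#' Deconvolve a BOLD series to the neural level
#'
#' Ridge-regularized least-squares inversion of the HRF convolution
#' operator at scan resolution: the series is mean-centred, the convolution
#' matrix `C` is built from the canonical HRF sampled at the TR, and the
#' neural series solves `(C'C + lambda I) x = C'y`. Reconvolving the
#' estimate approximates the input.
#'
#' @param series Per-scan BOLD series (one run).
#' @param hrf An [hrf_model()].
#' @param ridge_lambda Nonnegative ridge penalty (default 1e-2).
#' @return Neural-level series (same length), with attribute `fitted` (the
#'   reconvolved estimate plus the series mean).
#' @export
deconvolve_neural <- function(series, hrf = hrf_model(),
                              ridge_lambda = 1e-2) {
  if (ridge_lambda < 0) stop("ridge_lambda must be nonnegative")
  if (!all(is.finite(series))) stop("series must be finite")
  n <- length(series)
  Cm <- hrf_convolution_matrix(n, hrf)
  H <- deconv_operator(n, hrf, ridge_lambda)
  y <- series - mean(series)
  x <- drop(H %*% y)
  attr(x, "fitted") <- drop(Cm %*% x) + mean(series)
  x
}

# kernel sampled at scan resolution; lower-triangular Toeplitz
hrf_convolution_matrix <- function(n, hrf) {
  key <- paste0("conv_", n, "_", hrf$tr_s, "_", hrf$length_s)
  if (!is.null(.traitscan_cache[[key]])) return(.traitscan_cache[[key]])
  fine <- canonical_hrf(hrf)
  k <- fine[1L + (seq_len(min(n, floor(hrf$length_s / hrf$tr_s) + 1L)) - 1L) *
              hrf$oversampling]
  Cm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    len <- min(length(k), n - j + 1L)
    Cm[j:(j + len - 1L), j] <- k[seq_len(len)]
  }
  .traitscan_cache[[key]] <- Cm
  Cm
}

deconv_operator <- function(n, hrf, lambda) {
  key <- paste0("deconv_", n, "_", hrf$tr_s, "_", lambda)
  if (!is.null(.traitscan_cache[[key]])) return(.traitscan_cache[[key]])
  Cm <- hrf_convolution_matrix(n, hrf)
  H <- solve(crossprod(Cm) + lambda * diag(n), t(Cm))
  .traitscan_cache[[key]] <- H
  H
}

#' Build a generalized PPI design matrix
#'
#' One PPI interaction column per task condition: the neural-level seed
#' series is step-upsampled to the oversampled grid, multiplied by the
#' condition's event indicator there, reconvolved with the HRF and sampled
#' at scan times. Psychological columns are the usual HRF-convolved
#' condition regressors, the physiological column is the observed seed
#' series (mean-centred), and motion and run intercepts are appended as in
#' the first-level GLM.
#'
#' @param neural Neural-level series: one vector per run (list), or a single
#'   vector for a one-run design.
#' @param events Event tibble (`run`, `onset`, `duration`, `condition`).
#' @param hrf An [hrf_model()].
#' @param motion Optional motion regressors as in [build_design_matrix()].
#' @param seed_series Observed seed BOLD series (same layout as `neural`);
#'   defaults to the reconvolved neural series.
#' @return Design matrix with labelled columns (`run<r>_ppi_<condition>`,
#'   `run<r>_<condition>`, `run<r>_phys`, motion, intercepts).
#' @export
build_gppi_design <- function(neural, events, hrf = hrf_model(),
                              motion = NULL, seed_series = NULL) {
  if (!is.list(neural)) neural <- list(neural)
  runs <- sort(unique(events$run))
  if (length(neural) != length(runs))
    stop("need one neural series per run")
  n_scans <- length(neural[[1]])
  if (!is.null(seed_series) && !is.list(seed_series))
    seed_series <- list(seed_series)
  if (is.matrix(motion)) {
    if (nrow(motion) != n_scans * length(runs) || ncol(motion) != 6)
      stop("motion must be (n_scans * n_runs) x 6")
    motion <- lapply(seq_along(runs), function(r)
      motion[(r - 1) * n_scans + seq_len(n_scans), , drop = FALSE])
  }
  conds <- emotion_conditions()
  kern <- canonical_hrf(hrf)
  os <- hrf$oversampling
  dt <- hrf$tr_s / os
  scan_idx <- 1L + (seq_len(n_scans) - 1L) * os
  blocks <- lapply(seq_along(runs), function(r) {
    ev <- events[events$run == runs[r], , drop = FALSE]
    if (length(neural[[r]]) != n_scans) stop("neural length mismatch")
    n_fine <- n_scans * os
    neural_fine <- rep(neural[[r]], each = os)
    ppi <- matrix(0, n_scans, length(conds),
                  dimnames = list(NULL, paste0("ppi_", conds)))
    for (ci in seq_along(conds)) {
      rows <- which(ev$condition == conds[ci])
      if (!length(rows)) next               # no events: PPI column stays 0
      ind <- numeric(n_fine)
      ind[1L + floor(ev$onset[rows] / dt)] <- 1
      prod_fine <- neural_fine * ind
      conv <- stats::convolve(prod_fine, rev(kern),
                              type = "open")[seq_len(n_fine)]
      ppi[, ci] <- conv[scan_idx]
    }
    ev0 <- ev; if (nrow(ev0)) ev0$duration <- 0
    psych <- convolve_conditions(ev0, n_scans, hrf, conds)
    phys <- if (is.null(seed_series)) {
      Cm <- hrf_convolution_matrix(n_scans, hrf)
      drop(Cm %*% neural[[r]])
    } else seed_series[[r]] - mean(seed_series[[r]])
    mot <- if (is.null(motion)) matrix(0, n_scans, 0) else {
      m <- motion[[r]]; colnames(m) <- paste0("mot", 1:6); m
    }
    blk <- cbind(ppi, psych, phys = phys, mot, intercept = 1)
    colnames(blk) <- paste0("run", runs[r], "_", colnames(blk))
    blk
  })
  X <- matrix(0, n_scans * length(runs),
              sum(vapply(blocks, ncol, 1L)))
  cn <- character(0); j <- 0L
  for (r in seq_along(runs)) {
    nc <- ncol(blocks[[r]])
    X[(r - 1) * n_scans + seq_len(n_scans), j + seq_len(nc)] <- blocks[[r]]
    cn <- c(cn, colnames(blocks[[r]])); j <- j + nc
  }
  colnames(X) <- cn
  X
}

#' Per-subject PPI coupling contrast map
#'
#' Fits the gPPI design at every in-mask voxel by OLS and returns the
#' angry-PPI minus neutral-PPI beta difference, the condition-specific
#' coupling contrast entered into the group genotype-by-trait model.
#'
#' @param bold Scans x voxels matrix (or 4-D array).
#' @param design gPPI design from [build_gppi_design()].
#' @param grid The [volume_grid()].
#' @param plus,minus PPI conditions contrasted.
#' @return Numeric per-voxel coupling contrast with attribute `grid`.
#' @export
ppi_coupling_map <- function(bold, design, grid, plus = "angry",
                             minus = "neutral") {
  fit <- fit_glm(bold, design, grid)
  contrast_map(fit, contrast_weights(design, paste0("ppi_", plus),
                                     paste0("ppi_", minus)))
}

#' gPPI coupling maps for a synthetic cohort
#'
#' Runs the full per-subject gPPI chain (simulate BOLD, extract the seed
#' series, ridge-deconvolve per run, build the generalized PPI design, fit,
#' contrast angry vs neutral PPI) and stacks the per-subject coupling maps.
#'
#' @param cohort A `synthetic_cohort`.
#' @param seed A [seed_spec()]; by default a sphere at the centroid of the
#'   cohort's `coupling_seed_region`.
#' @param ridge_lambda Deconvolution ridge penalty.
#' @return A `coupling_maps` object (subjects x voxels matrix with
#'   attributes `grid`, `subject_id`, `seed`).
#' @export
fit_gppi <- function(cohort, seed = NULL, ridge_lambda = 1e-2) {
  spec <- cohort$spec
  grid <- spec$grid
  if (is.null(seed)) {
    if (!length(spec$coupling_seed_region))
      stop("no seed region in the cohort spec; supply `seed`")
    ijk <- colMeans(arrayInd(spec$coupling_seed_region, grid$dim))
    seed <- seed_spec("seed_region", drop(ijk_to_mm(grid, round(ijk))),
                      radius_mm = 2 * min(grid$voxel_size_mm))
  }
  n_scans <- spec$volumes_per_run
  n <- spec$n_subjects
  maps <- matrix(0, n, sum(grid$mask))
  for (i in seq_len(n)) {
    sub <- simulate_subject_bold(cohort, i)
    ts_all <- extract_seed_timeseries(sub$bold, grid, seed)
    runs <- seq_len(spec$n_runs)
    ts_run <- lapply(runs, function(r)
      ts_all[(r - 1) * n_scans + seq_len(n_scans)])
    neural <- lapply(ts_run, deconvolve_neural, hrf = cohort$hrf,
                     ridge_lambda = ridge_lambda)
    X <- build_gppi_design(neural, cohort$schedule, cohort$hrf,
                           motion = sub$motion, seed_series = ts_run)
    maps[i, ] <- ppi_coupling_map(sub$bold, X, grid)
  }
  structure(maps, grid = grid, seed = seed,
            subject_id = cohort$phenotypes$subject_id,
            contrast = "ppi_angry>ppi_neutral",
            class = c("coupling_maps", "matrix", "array"))
}
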
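#' Canonical HRF model
#'
#' Parameters of the canonical double-gamma hemodynamic response function:
#' a positive gamma peaking around 5 s minus a scaled, delayed gamma
#' undershoot. The sampled kernel is normalized to a maximum of 1.
#'
#' @param tr_s Repetition time (s).
#' @param oversampling Samples per TR on the fine (neural) time grid.
#' @param peak_delay,undershoot_delay Gamma shape parameters of response and
#'   undershoot (with scale = the corresponding dispersion, the response
#'   mode sits near `(peak_delay - 1) * dispersion` seconds).
#' @param dispersion Length-2 gamma scale parameters (s).
#' @param undershoot_ratio Peak:undershoot amplitude ratio denominator
#'   (undershoot is divided by this).
#' @param length_s Kernel support (s); covers the full undershoot.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(tr_s = 2, oversampling = 16,
                      peak_delay = 6, undershoot_delay = 16,
                      dispersion = c(1, 1), undershoot_ratio = 6,
                      length_s = 32) {
  if (tr_s <= 0) stop("tr_s must be positive")
  stopifnot(oversampling >= 1, length_s > 0, all(dispersion > 0))
  structure(list(tr_s = tr_s, oversampling = as.integer(oversampling),
                 peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 dispersion = dispersion,
                 undershoot_ratio = undershoot_ratio, length_s = length_s),
            class = "hrf_model")
}

hrf_support_s <- function() 32

#' Sample the canonical double-gamma HRF
#'
#' @param model An [hrf_model()].
#' @return Numeric kernel sampled every `tr_s / oversampling` seconds from 0
#'   to `length_s`, maximum exactly 1, with attribute `dt` (the sampling
#'   step). A late negative undershoot is present.
#' @export
#' @examples
#' k <- canonical_hrf(hrf_model())
#' attr(k, "dt")
canonical_hrf <- function(model = hrf_model()) {
  stopifnot(inherits(model, "hrf_model"))
  dt <- model$tr_s / model$oversampling
  t <- seq(0, model$length_s, by = dt)
  k <- stats::dgamma(t, shape = model$peak_delay,
                     scale = model$dispersion[1]) -
    stats::dgamma(t, shape = model$undershoot_delay,
                  scale = model$dispersion[2]) / model$undershoot_ratio
  k <- k / max(k)
  attr(k, "dt") <- dt
  k
}

# Convolve per-run event sticks/boxcars with the HRF on the fine grid and
# sample at scan acquisition times. Returns n_scans x n_conditions matrix.
convolve_conditions <- function(events_run, n_scans, model,
                                conditions = emotion_conditions(),
                                amplitudes = NULL) {
  dt <- model$tr_s / model$oversampling
  n_fine <- n_scans * model$oversampling
  kern <- canonical_hrf(model)
  out <- matrix(0, n_scans, length(conditions),
                dimnames = list(NULL, conditions))
  scan_idx <- 1L + (seq_len(n_scans) - 1L) * model$oversampling
  for (ci in seq_along(conditions)) {
    rows <- which(events_run$condition == conditions[ci])
    if (!length(rows)) next
    stick <- numeric(n_fine)
    for (r in rows) {
      a <- if (is.null(amplitudes)) 1 else amplitudes[r]
      i0 <- 1L + floor(events_run$onset[r] / dt)
      i1 <- max(i0, 1L + floor((events_run$onset[r] +
                                  events_run$duration[r]) / dt) - 1L)
      if (events_run$duration[r] <= 0) i1 <- i0
      if (i1 > n_fine) stop("event past the last scan")
      stick[i0:i1] <- stick[i0:i1] + a
    }
    conv <- stats::convolve(stick, rev(kern), type = "open")[seq_len(n_fine)]
    out[, ci] <- conv[scan_idx]
  }
  out
}

#' Build a first-level design matrix
#'
#' One HRF-convolved regressor per condition per run (stimuli modelled as
#' 0-duration impulses by default, configurable via the event table's
#' `duration` column), six motion nuisance columns per run appended
#' verbatim, and one intercept per run; runs are assembled block-diagonally
#' for a joint fit.
#'
#' @param events Event tibble (`run`, `onset`, `duration`, `condition`).
#' @param n_scans Scans per run.
#' @param hrf An [hrf_model()].
#' @param motion Optional scans-x-6 motion matrix per run (a list with one
#'   matrix per run, or a single `(n_scans * n_runs) x 6` matrix), or `NULL`
#'   to omit motion columns.
#' @param impulse If `TRUE` (default), events are modelled as 0-duration
#'   impulses regardless of the `duration` column.
#'
#' @return Numeric matrix `(n_scans * n_runs) x p` with labelled columns
#'   (`run<r>_<condition>`, `run<r>_mot<1..6>`, `run<r>_intercept`) and
#'   attributes `conditions`, `n_runs`, `n_scans`.
#' @export
build_design_matrix <- function(events, n_scans, hrf = hrf_model(),
                                motion = NULL, impulse = TRUE) {
  runs <- if (nrow(events)) sort(unique(events$run)) else 1L
  n_runs <- length(runs)
  if (max(events$onset %||% 0) > n_scans * hrf$tr_s)
    stop("event past the last scan")
  if (is.matrix(motion)) {
    if (nrow(motion) != n_scans * n_runs || ncol(motion) != 6)
      stop("motion must be (n_scans * n_runs) x 6")
    motion <- lapply(seq_len(n_runs), function(r)
      motion[(r - 1) * n_scans + seq_len(n_scans), , drop = FALSE])
  }
  conditions <- emotion_conditions()
  blocks <- lapply(seq_len(n_runs), function(r) {
    ev <- events[events$run == runs[r], , drop = FALSE]
    if (impulse && nrow(ev)) ev$duration <- 0
    present <- intersect(conditions, unique(ev$condition))
    cond <- if (length(present))
      convolve_conditions(ev, n_scans, hrf, present) else
        matrix(0, n_scans, 0)
    mot <- if (is.null(motion)) matrix(0, n_scans, 0) else {
      m <- motion[[r]]
      if (nrow(m) != n_scans || ncol(m) != 6)
        stop("motion must be (n_scans * n_runs) x 6")
      colnames(m) <- paste0("mot", 1:6)
      m
    }
    blk <- cbind(cond, mot, intercept = 1)
    colnames(blk) <- paste0("run", runs[r], "_", colnames(blk))
    blk
  })
  X <- matrix(0, n_scans * n_runs, sum(vapply(blocks, ncol, 1L)))
  cn <- character(0)
  j <- 0L
  for (r in seq_len(n_runs)) {
    nc <- ncol(blocks[[r]])
    X[(r - 1) * n_scans + seq_len(n_scans), j + seq_len(nc)] <- blocks[[r]]
    cn <- c(cn, colnames(blocks[[r]]))
    j <- j + nc
  }
  colnames(X) <- cn
  structure(X, conditions = conditions, n_runs = n_runs, n_scans = n_scans)
}

#' Fit per-voxel ordinary-least-squares GLMs
#'
#' @param bold BOLD data: a scans-x-voxels matrix over the in-mask voxels of
#'   `grid`, or a 4-D array (x, y, z, scan) which is masked first.
#' @param X Design matrix from [build_design_matrix()]; must be full column
#'   rank with rows matching the scan count.
#' @param grid The [volume_grid()] carrying the analysis mask.
#' @return A `glm_fit` object: `coefficients` (p x voxels), `sigma2`
#'   (residual variance per voxel), `df_residual`, `design`, `grid`.
#' @export
fit_glm <- function(bold, X, grid) {
  if (is.array(bold) && length(dim(bold)) == 4) {
    stopifnot(all(dim(bold)[1:3] == grid$dim))
    bold <- t(apply(bold, 4, function(v) v[grid$mask]))
    if (sum(grid$mask) == 1) bold <- t(bold)
  }
  stopifnot(is.matrix(bold))
  if (nrow(bold) != nrow(X)) stop("scan count does not match design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qx, bold)
  resid <- bold - X %*% beta
  df <- nrow(X) - ncol(X)
  structure(list(coefficients = beta,
                 sigma2 = colSums(resid^2) / max(df, 1),
                 df_residual = df, design = X, grid = grid),
            class = "glm_fit")
}

#' Contrast weights across runs
#'
#' Builds a per-regressor weight vector giving `+1/n_runs` to each run's
#' `plus` condition column and `-1/n_runs` to each `minus` column.
#'
#' @param X Design matrix from [build_design_matrix()].
#' @param plus,minus Condition names.
#' @return Named numeric weight vector of length `ncol(X)`.
#' @export
contrast_weights <- function(X, plus = "angry", minus = "neutral") {
  cn <- colnames(X)
  w <- stats::setNames(numeric(length(cn)), cn)
  ip <- grep(paste0("_", plus, "$"), cn)
  im <- grep(paste0("_", minus, "$"), cn)
  if (!length(ip) || !length(im)) stop("contrast condition not in design")
  w[ip] <- 1 / length(ip)
  w[im] <- -1 / length(im)
  w
}

#' Compute a contrast map
#'
#' Voxelwise weighted sum of GLM coefficients, e.g. the angry > neutral
#' beta-difference image that feeds the searchlight.
#'
#' @param fit A `glm_fit` (or a bare p x voxels coefficient matrix).
#' @param weights Per-regressor weights (length = regressor count), e.g.
#'   from [contrast_weights()].
#' @return Numeric vector over in-mask voxels with attribute `grid`.
#' @export
contrast_map <- function(fit, weights) {
  beta <- if (inherits(fit, "glm_fit")) fit$coefficients else fit
  if (length(weights) != nrow(beta))
    stop("weight length must equal the regressor count")
  v <- drop(crossprod(beta, weights))
  if (inherits(fit, "glm_fit")) attr(v, "grid") <- fit$grid
  v
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
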
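#' Integer lattice offsets of a searchlight sphere
#'
#' All integer 3-vectors with Euclidean norm at most `radius_vox`, centre
#' included, in deterministic lexicographic order. Symmetric under negation.
#'
#' @param radius_vox Nonnegative sphere radius in voxel units.
#' @return Integer matrix (n_offsets x 3).
#' @export
#' @examples
#' nrow(sphere_offsets(1)) # 7: centre + 6 face neighbours
sphere_offsets <- function(radius_vox) {
  if (length(radius_vox) != 1 || radius_vox < 0)
    stop("radius must be a nonnegative scalar")
  r <- floor(radius_vox)
  g <- seq.int(-r, r)
  off <- as.matrix(expand.grid(z = g, y = g, x = g))[, 3:1, drop = FALSE]
  off <- off[off[, 1]^2 + off[, 2]^2 + off[, 3]^2 <= radius_vox^2, ,
             drop = FALSE]
  off <- off[order(off[, 1], off[, 2], off[, 3]), , drop = FALSE]
  dimnames(off) <- list(NULL, c("di", "dj", "dk"))
  storage.mode(off) <- "integer"
  off
}

#' Balanced random k-fold partition
#'
#' Randomly assigns `n` subjects to `k` folds whose sizes differ by at most
#' one (e.g. 229 subjects into 10 folds of 22 or 23).
#'
#' @param n Number of subjects.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
kfold_partition <- function(n, k, seed = 1L) {
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  withr::with_seed(as.integer(seed), sample(rep(seq_len(k), sizes)))
}

#' Train and evaluate a linear epsilon-insensitive SVR
#'
#' Fits a linear support vector regression (primal
#' `0.5 ||w||^2 + C * sum(eps-insensitive losses)`) on the training set and
#' returns predictions for the test set. A constant training target is
#' returned unchanged (the flat function attains zero loss).
#'
#' @param train_X,test_X Numeric feature matrices (subjects x features).
#' @param train_y Training trait scores.
#' @param C Box constraint (default 1).
#' @param epsilon Insensitivity width (default 0.1).
#' @param scale_features Z-score columns using training-set statistics.
#' @return Numeric predictions, one per test row.
#' @export
svr_train_predict <- function(train_X, train_y, test_X, C = 1,
                              epsilon = 0.1, scale_features = FALSE) {
  train_X <- rbind(train_X); test_X <- rbind(test_X)
  if (!nrow(train_X) || !length(train_y)) stop("empty training set")
  if (nrow(train_X) < 2) stop("need at least 2 training subjects")
  if (ncol(train_X) != ncol(test_X)) stop("feature counts do not match")
  if (!all(is.finite(train_X)) || !all(is.finite(test_X)))
    stop("non-finite features")
  if (stats::sd(train_y) == 0) return(rep(train_y[1], nrow(test_X)))
  if (scale_features) {
    mu <- colMeans(train_X)
    sdv <- apply(train_X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    train_X <- sweep(sweep(train_X, 2, mu), 2, sdv, `/`)
    test_X <- sweep(sweep(test_X, 2, mu), 2, sdv, `/`)
  }
  fit <- e1071::svm(train_X, train_y, type = "eps-regression",
                    kernel = "linear", cost = C, epsilon = epsilon,
                    scale = FALSE)
  unname(stats::predict(fit, test_X))
}

#' Searchlight analysis settings
#'
#' @param radius_vox Sphere radius in voxel units (default 3; 123 offsets).
#' @param svr_cost SVR box constraint C (default 1).
#' @param svr_epsilon SVR insensitivity width (default 0.1).
#' @param n_folds Cross-validation folds (default 10).
#' @param cv_seed Seed for the single fold assignment shared by all centres.
#' @param min_voxels Minimum in-mask sphere members to attempt a fit.
#' @param fdr_q Per-map FDR level (default 0.0125 = family 0.05 over the 4
#'   emotion contrasts, two-sided).
#' @param scale_features Z-score features within training folds.
#' @param center_folds Remove each fold's mean prediction before pooling
#'   (default `TRUE`). Pooled out-of-fold predictions carry a spurious
#'   anti-correlation with the outcome because each training set excludes
#'   its test fold; centring restores the nominal null distribution of r.
#' @param p_method How per-centre p-values are computed. `"fold_t"`
#'   (default): the per-fold prediction-outcome correlations are combined by
#'   the variance-corrected resampled t-test (Nadeau-Bengio inflation
#'   `1/k + n_test/n_train`, k - 1 df), which is null-calibrated for
#'   cross-validated predictions; `"t"`: the two-sided t transform of the
#'   pooled r with n - 2 df (anticonservative under the null because pooled
#'   out-of-fold predictions are not independent of the outcome);
#'   `"permutation"`: label-shuffling p-values (slower by a factor
#'   `n_perm`).
#' @param n_perm Number of label permutations when
#'   `p_method = "permutation"`.
#' @return An object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_vox = 3, svr_cost = 1,
                             svr_epsilon = 0.1, n_folds = 10, cv_seed = 1L,
                             min_voxels = 10, fdr_q = per_map_q(),
                             scale_features = FALSE, center_folds = TRUE,
                             p_method = c("fold_t", "t", "permutation"),
                             n_perm = 1000) {
  stopifnot(radius_vox >= 0, svr_cost > 0, svr_epsilon >= 0, n_folds >= 2,
            n_perm >= 1)
  structure(list(radius_vox = radius_vox, svr_cost = svr_cost,
                 svr_epsilon = svr_epsilon, n_folds = as.integer(n_folds),
                 cv_seed = as.integer(cv_seed),
                 min_voxels = as.integer(min_voxels), fdr_q = fdr_q,
                 scale_features = scale_features,
                 center_folds = center_folds,
                 p_method = match.arg(p_method),
                 n_perm = as.integer(n_perm)),
            class = "searchlight_spec")
}

#' Per-map FDR level from a family level
#'
#' Splits a family-wise FDR budget evenly over the emotion contrasts:
#' family 0.05 over 4 contrasts gives the per-map q = 0.0125 used to
#' threshold each prediction map.
#'
#' @param q_family Family-level FDR budget.
#' @param n_contrasts Number of contrast maps in the family.
#' @return The per-map q.
#' @export
per_map_q <- function(q_family = 0.05, n_contrasts = 4) {
  stopifnot(q_family > 0, q_family < 1, n_contrasts >= 1)
  q_family / n_contrasts
}

# neighbour lookup: V x n_offsets matrix of in-mask column indices (0 =
# outside grid or mask)
sphere_neighbours <- function(grid, radius_vox) {
  off <- sphere_offsets(radius_vox)
  vox <- which(grid$mask)
  ijk <- arrayInd(vox, grid$dim)
  lut <- integer(prod(grid$dim))
  lut[vox] <- seq_along(vox)
  V <- length(vox)
  nb <- matrix(0L, V, nrow(off))
  for (m in seq_len(nrow(off))) {
    ni <- ijk[, 1] + off[m, 1]
    nj <- ijk[, 2] + off[m, 2]
    nk <- ijk[, 3] + off[m, 3]
    ok <- ni >= 1 & ni <= grid$dim[1] & nj >= 1 & nj <= grid$dim[2] &
      nk >= 1 & nk <= grid$dim[3]
    lin <- ni[ok] + grid$dim[1] * (nj[ok] - 1) +
      grid$dim[1] * grid$dim[2] * (nk[ok] - 1)
    nb[ok, m] <- lut[lin]
  }
  nb
}

#' Searchlight SVR decoding of a trait from contrast maps
#'
#' For every in-mask centre voxel, takes the in-mask voxels of the
#' surrounding sphere as features, predicts each subject's trait score by
#' linear SVR under a single k-fold cross-validation partition shared by all
#' centres, pools the out-of-fold predictions (fold-mean-centred by
#' default, see [searchlight_spec()]), and scores the centre by the Pearson
#' correlation between pooled predictions and observed traits. Per-centre
#' p-values come from the variance-corrected resampled t-test over the
#' per-fold correlations by default (see [searchlight_spec()] for the
#' plain n - 2 df t transform and permutation alternatives). The resulting
#' p map is thresholded by Benjamini-Hochberg FDR at `spec$fdr_q`.
#'
#' @param maps A [contrast_maps()] collection (subjects x voxels).
#' @param traits Per-subject trait scores (non-constant).
#' @param spec A [searchlight_spec()].
#' @return A `prediction_map`: tibble with per-voxel `r`, `p`, `fdr_sig`,
#'   `n_features` and coordinates; attributes `spec`, `critical_p`,
#'   `contrast`, `grid`, `folds`.
#' @export
searchlight_predict <- function(maps, traits, spec = searchlight_spec()) {
  stopifnot(inherits(maps, "contrast_maps"),
            inherits(spec, "searchlight_spec"))
  grid <- attr(maps, "grid")
  n <- nrow(maps)
  if (length(traits) != n) stop("traits must match the subject count")
  if (stats::sd(traits) == 0) stop("degenerate target: traits are constant")
  if (spec$n_folds > n) stop("fewer subjects than folds")
  nb <- sphere_neighbours(grid, spec$radius_vox)
  V <- nrow(nb)
  folds <- kfold_partition(n, spec$n_folds, spec$cv_seed)
  nf <- vapply(seq_len(V), function(v) sum(nb[v, ] > 0L), 1L)
  obs <- searchlight_r(maps, traits, spec, nb, folds)
  r <- obs$r
  if (spec$p_method %in% c("t", "fold_t")) {
    p <- obs$p
  } else {
    exceed <- integer(V)
    perm_y <- withr::with_seed(spec$cv_seed + 1L,
                               replicate(spec$n_perm, sample(traits),
                                         simplify = FALSE))
    for (b in seq_len(spec$n_perm)) {
      rb <- searchlight_r(maps, perm_y[[b]], spec, nb, folds)$r
      exceed <- exceed + as.integer(!is.na(rb) & !is.na(r) &
                                      abs(rb) >= abs(r))
    }
    p <- ifelse(is.na(r), NA_real_, (1 + exceed) / (spec$n_perm + 1))
  }
  defined <- !is.na(p)
  fdr <- fdr_threshold(p[defined], spec$fdr_q)
  sig <- rep(FALSE, V)
  sig[defined] <- fdr$significant
  idx <- grid_index(grid)
  out <- tibble::tibble(idx, n_features = nf, r = r, p = p, fdr_sig = sig)
  structure(out, spec = spec, critical_p = fdr$critical_p,
            contrast = attr(maps, "contrast"), grid = grid, folds = folds,
            n_subjects = n,
            class = c("prediction_map", class(tibble::tibble())))
}

# one pass of the searchlight for a given target vector: per-centre pooled
# cross-validated SVR predictions and their correlation with the target
searchlight_r <- function(maps, y, spec, nb, folds) {
  n <- nrow(maps)
  V <- nrow(nb)
  k <- spec$n_folds
  r <- rep(NA_real_, V); p <- rep(NA_real_, V)
  n_te <- tabulate(folds, k)
  nb_factor <- sqrt(1 / k + mean(n_te) / (n - mean(n_te)))
  for (v in seq_len(V)) {
    feats <- nb[v, ]
    feats <- feats[feats > 0L]
    if (length(feats) < spec$min_voxels) next
    X <- maps[, feats, drop = FALSE]
    pred <- numeric(n)
    for (f in seq_len(k)) {
      te <- folds == f
      pred[te] <- svr_train_predict(X[!te, , drop = FALSE], y[!te],
                                    X[te, , drop = FALSE],
                                    C = spec$svr_cost,
                                    epsilon = spec$svr_epsilon,
                                    scale_features = spec$scale_features)
    }
    r_fold <- vapply(seq_len(k), function(f) {
      te <- folds == f
      if (stats::sd(pred[te]) < 1e-12 || stats::sd(y[te]) == 0) 0 else
        stats::cor(pred[te], y[te])
    }, numeric(1))
    if (spec$center_folds)
      for (f in seq_len(k)) {
        te <- folds == f
        pred[te] <- pred[te] - mean(pred[te])
      }
    rp <- prediction_outcome_r(pred, y)
    r[v] <- rp[1]
    if (spec$p_method == "fold_t") {
      se <- stats::sd(r_fold) * nb_factor
      p[v] <- if (se < 1e-12) 1 else
        2 * stats::pt(-abs(mean(r_fold) / se), k - 1)
    } else {
      p[v] <- rp[2]
    }
  }
  list(r = r, p = p)
}

# pooled prediction-outcome correlation and two-sided t-transform p
prediction_outcome_r <- function(pred, y) {
  n <- length(y)
  if (stats::sd(pred) < 1e-12) return(c(0, 1))
  r <- stats::cor(pred, y)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) return(c(r, .Machine$double.xmin))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r, 2 * stats::pt(-abs(tt), n - 2))
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up procedure within the mask: with ordered p-values `p(1) <= ... <=
#' p(m)`, all `p <= p(k*)` are flagged where `k* = max{i : p(i) <= (i/m) q}`;
#' nothing is flagged when no `i` qualifies.
#'
#' @param p_values Per-voxel p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @return List with `significant` (logical), `critical_p` (the step-up
#'   cutoff, 0 when nothing is flagged), and `q`.
#' @export
fdr_threshold <- function(p_values, q = per_map_q()) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 1)) stop("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  sig <- stats::p.adjust(p_values, method = "BH") <= q
  list(significant = sig,
       critical_p = if (any(sig)) max(p_values[sig]) else 0,
       q = q)
}
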
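# small fixtures built in code, shared across test files

tiny_grid <- function(dim = c(10, 10, 10), mask_radius = 3.2) {
  traitscan:::default_grid(dim, mask_radius_vox = mask_radius)
}

# a small cohort with a pattern region, short runs, fast to simulate
tiny_pattern_spec <- function(n = 8, noise_sd = 0.5, strength = 0.3,
                              seed = 3) {
  g <- tiny_grid()
  cohort_spec(n_subjects = n, grid = g, volumes_per_run = 160,
              noise_sd = noise_sd,
              pattern_region = voxel_ball(g, c(5, 5, 5), 2),
              pattern_strength = strength, rng_seed = seed)
}

tiny_coupling_spec <- function(n = 8, noise_sd = 0.5, slope = 0.5,
                               seed = 5) {
  g <- tiny_grid(c(12, 12, 12), mask_radius = 4)
  cohort_spec(n_subjects = n, grid = g, volumes_per_run = 160,
              noise_sd = noise_sd,
              coupling_seed_region = voxel_ball(g, c(4, 6, 6), 1),
              coupling_target_region = voxel_ball(g, c(9, 6, 6), 1),
              coupling_slopes = c(carrier = -slope, noncarrier = slope),
              coupling_base = 0.3, rng_seed = seed)
}

# literal Benjamini-Hochberg step-up, straight from the definition
bh_stepup <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * q)
  flag <- rep(FALSE, m)
  if (length(k)) flag[o[seq_len(max(k))]] <- TRUE
  flag
}

# independent linear epsilon-SVR via the dual QP (kernlab::ipop)
svr_qp_oracle <- function(X, y, Xte, C = 1, epsilon = 0.1) {
  n <- nrow(X)
  K <- X %*% t(X)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  cvec <- c(epsilon - y, epsilon + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sv <- kernlab::ipop(cvec, H, A, 0, rep(0, 2 * n), rep(C, 2 * n), 0,
                      sigf = 9)
  a <- kernlab::primal(sv)
  alpha <- a[1:n] - a[(n + 1):(2 * n)]
  w <- drop(t(X) %*% alpha)
  free_up <- a[1:n] > 1e-6 & a[1:n] < C - 1e-6
  free_dn <- a[(n + 1):(2 * n)] > 1e-6 & a[(n + 1):(2 * n)] < C - 1e-6
  b <- if (any(free_up)) mean((y - X %*% w - epsilon)[free_up]) else
    mean((y - X %*% w + epsilon)[free_dn])
  drop(Xte %*% w + b)
}

# manual pooled cross-validated SVR correlation matching the package default
manual_cv_r <- function(X, y, folds, k, center = TRUE) {
  n <- length(y)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- folds == f
    pred[te] <- svr_train_predict(X[!te, , drop = FALSE], y[!te],
                                  X[te, , drop = FALSE])
  }
  if (center)
    for (f in seq_len(k)) {
      te <- folds == f
      pred[te] <- pred[te] - mean(pred[te])
    }
  stats::cor(pred, y)
}
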
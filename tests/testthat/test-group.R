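test_that("interaction design uses centred +/- 1/2 coding", {
  carriers <- rep(c(0, 1), each = 10)
  traits <- rnorm(20, 21, 5)
  X <- build_interaction_design(carriers, traits)
  expect_equal(colnames(X), c("intercept", "group", "trait_c",
                              "interaction"))
  expect_equal(sum(X[, "group"]), 0)                   # balanced +-1/2
  expect_equal(mean(X[, "trait_c"]), 0)
  expect_equal(X[, "interaction"], X[, "group"] * X[, "trait_c"])
  expect_equal(qr(X)$rank, 4)
  expect_error(build_interaction_design(rep(1, 10), rnorm(10)),
               "at least 2")
  expect_error(build_interaction_design(c(0, rep(1, 9)), rnorm(10)),
               "at least 2")
})

test_that("interaction t matches a hand-computed small-sample OLS", {
  carriers <- c(0, 0, 0, 0, 1, 1, 1, 1)
  traits <- c(15, 18, 24, 27, 16, 19, 23, 28)
  y <- c(0.2, 0.5, 0.9, 1.4, 1.1, 0.8, 0.3, -0.2)
  X <- build_interaction_design(carriers, traits)
  sm <- interaction_tmap(matrix(y, ncol = 1), X)
  # independent closed-form oracle via base lm
  g <- ifelse(carriers == 1, 0.5, -0.5)
  tc <- traits - mean(traits)
  lmfit <- summary(lm(y ~ g + tc + I(g * tc)))
  expect_equal(sm$t, lmfit$coefficients["I(g * tc)", "t value"],
               tolerance = 1e-8)
  expect_equal(sm$p, lmfit$coefficients["I(g * tc)", "Pr(>|t|)"],
               tolerance = 1e-8)
  expect_equal(attr(sm, "df"), 4)
})

test_that("null interaction t follows the central t distribution", {
  set.seed(21)
  n <- 40
  carriers <- rep(c(0, 1), each = n / 2)
  traits <- rnorm(n, 21, 5)
  X <- build_interaction_design(carriers, traits)
  tvals <- replicate(60, {
    Y <- matrix(rnorm(n * 25), n)
    interaction_tmap(Y, X)$t
  })
  ks <- ks.test(as.numeric(tvals), function(q) pt(q, n - 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation FWE dominates uncorrected p and hits its floor", {
  set.seed(22)
  n <- 30
  carriers <- rep(c(0, 1), each = n / 2)
  traits <- rnorm(n, 21, 5)
  X <- build_interaction_design(carriers, traits)
  Y <- matrix(rnorm(n * 40), n)
  # plant a huge interaction effect in one voxel
  Y[, 7] <- Y[, 7] + X[, "interaction"] * 5
  p_fwe <- permutation_fwe(Y, X, n_perm = 199, seed = 3)
  sm <- interaction_tmap(Y, X)
  expect_true(all(p_fwe >= sm$p - 1e-12))
  expect_equal(min(p_fwe), 1 / 200)          # counting bound with +1
  expect_equal(which.min(p_fwe), 7L)
  expect_error(permutation_fwe(Y, X, n_perm = 10), "at least 100")
})

test_that("cluster labelling matches an igraph flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(23)
  g <- volume_grid(c(7, 7, 7))
  off <- traitscan:::connectivity_offsets(18)
  for (rep in 1:5) {
    sig <- array(runif(343) < 0.25, dim = c(7, 7, 7))
    tbl <- label_clusters(sig, g, min_k = 0)
    # oracle: connected components on the 18-neighbour adjacency graph
    vox <- which(sig)
    if (!length(vox)) { expect_equal(nrow(tbl), 0); next }
    ijk <- arrayInd(vox, c(7, 7, 7))
    edges <- NULL
    for (m in seq_len(nrow(off))) {
      nb <- sweep(ijk, 2, off[m, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= 7 & nb[, 2] >= 1 & nb[, 2] <= 7 &
        nb[, 3] >= 1 & nb[, 3] <= 7
      lin <- nb[ok, 1] + 7 * (nb[ok, 2] - 1) + 49 * (nb[ok, 3] - 1)
      hit <- lin %in% vox
      edges <- rbind(edges, cbind(vox[ok][hit], lin[hit]))
    }
    gr <- igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2), directed = FALSE)
    gr <- gr + igraph::vertices(setdiff(as.character(vox),
                                        igraph::V(gr)$name))
    comp <- igraph::components(gr)
    oracle_sizes <- sort(as.integer(comp$csize))
    expect_equal(sort(tbl$k), oracle_sizes)
  }
})

test_that("extent filtering and peak localisation behave as specified", {
  g <- volume_grid(c(8, 8, 8))
  sig <- array(FALSE, c(8, 8, 8))
  sig[4, 4, 4] <- TRUE                        # isolated voxel
  expect_equal(nrow(label_clusters(sig, g, min_k = 10)), 0)
  sig2 <- array(FALSE, c(8, 8, 8))
  sig2[3:5, 3:5, 3:5] <- TRUE                 # solid 3x3x3 block
  vals <- array(0, c(8, 8, 8)); vals[4, 5, 3] <- -9
  tbl <- label_clusters(sig2, g, values = vals, min_k = 10)
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$k, 27)
  expect_equal(c(tbl$peak_i, tbl$peak_j, tbl$peak_k), c(4, 5, 3))
  expect_equal(tbl$peak_stat, -9)
})

test_that("cluster estimates and slope reports behave correctly", {
  set.seed(24)
  Y <- matrix(rnorm(12 * 6), 12, 6)
  expect_equal(extract_cluster_estimates(Y, 3), Y[, 3])
  expect_equal(extract_cluster_estimates(Y, c(2, 5)),
               rowMeans(Y[, c(2, 5)]))
  expect_error(extract_cluster_estimates(Y, integer(0)), "empty")
  carriers <- rep(c(0, 1), each = 20)
  traits <- rnorm(40, 21, 5)
  est <- ifelse(carriers == 1, -0.1, 0.1) * (traits - 21) + rnorm(40, 0, 0.3)
  rep_tbl <- group_slope_report(est, traits, carriers, m = 8)
  expect_equal(rep_tbl$p_corrected, pmin(1, 8 * rep_tbl$p))
  expect_identical(attr(rep_tbl, "sign_opposition"),
                   prod(rep_tbl$slope_sign) < 0)
  expect_error(group_slope_report(est[1:4], traits[1:4], c(0, 0, 0, 1)),
               "at least 3")
  expect_error(group_slope_report(rep(1, 40), traits, carriers),
               "zero-variance")
})

test_that("opposite injected slopes are recovered with correct signs", {
  set.seed(25)
  hits <- replicate(40, {
    n <- 80
    carriers <- rbinom(n, 1, 0.5)
    if (min(table(carriers)) < 3) return(NA)
    z <- rnorm(n)
    est <- ifelse(carriers == 1, -0.4, 0.4) * z + rnorm(n) * sqrt(1 - 0.16)
    r <- group_slope_report(est, z, carriers)
    r$slope_sign[r$group == "noncarrier"] == 1 &&
      r$slope_sign[r$group == "carrier"] == -1
  })
  expect_gt(mean(hits, na.rm = TRUE), 0.9)
})

test_that("the full group stage recovers a planted interaction cluster", {
  sp <- coupling_cohort_spec(40, seed = 9)
  co <- simulate_cohort(sp)
  cpl <- fit_gppi(co)
  gi <- group_interaction(cpl, co$phenotypes, snp = sp$coupling_snp,
                          n_perm = 300, seed = 2)
  expect_gt(nrow(gi$clusters), 0)
  overlap <- length(intersect(gi$clusters$voxels[[1]],
                              sp$coupling_target_region))
  expect_gt(overlap, 0)
  expect_true(all(gi$clusters$k > 10))
  expect_equal(gi$clusters$p_corrected,
               pmin(1, 3 * gi$clusters$p_fwe))
  expect_true(attr(gi$reports[[1]], "sign_opposition"))
  td <- tidy(gi)
  expect_equal(nrow(td), nrow(gi$clusters))
  expect_named(td, c("region", "k", "t", "p_fwe", "p_corrected",
                     "x", "y", "z"))
})
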
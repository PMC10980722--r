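#' Build the genotype-by-trait group design
#'
#' Two-group moderation design: intercept, carrier indicator coded +1/2
#' (carrier) vs -1/2 (non-carrier), mean-centred trait, and their product
#' (formed after centring, so the main effects stay interpretable).
#'
#' @param carriers 0/1 carrier indicator per subject.
#' @param traits Trait scores per subject.
#' @return Numeric n x 4 design matrix with columns `intercept`, `group`,
#'   `trait_c`, `interaction`; full rank by construction.
#' @export
build_interaction_design <- function(carriers, traits) {
  stopifnot(length(carriers) == length(traits))
  if (!all(carriers %in% c(0, 1))) stop("carriers must be 0/1")
  if (min(table(factor(carriers, levels = c(0, 1)))) < 2)
    stop("each genotype group needs at least 2 subjects")
  g <- ifelse(carriers == 1, 0.5, -0.5)
  tc <- traits - mean(traits)
  X <- cbind(intercept = 1, group = g, trait_c = tc, interaction = g * tc)
  if (qr(X)$rank < 4) stop("group design is rank deficient")
  X
}

# per-voxel OLS t statistics for one coefficient of a shared design
ols_tmap <- function(Y, X, coef = ncol(X)) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  K <- XtXi %*% t(X)
  B <- K %*% Y
  rss <- colSums((Y - X %*% B)^2)
  df <- n - p
  se <- sqrt(pmax(rss, 0) / df * XtXi[coef, coef])
  t <- unname(B[coef, ] / se)
  list(t = t, df = df, beta = unname(B[coef, ]))
}

#' Voxelwise genotype-by-trait interaction t map
#'
#' Fits the group design at every voxel of the per-subject coupling maps by
#' OLS and returns the t statistic of the interaction coefficient
#' (df = n - 4) with its two-sided parametric p.
#'
#' @param coupling A [fit_gppi()] `coupling_maps` object or a bare
#'   subjects x voxels matrix.
#' @param design Group design from [build_interaction_design()].
#' @return A `stat_map` tibble: voxel coordinates (when a grid is attached),
#'   `t`, `p`; attributes `df`, `grid`.
#' @export
interaction_tmap <- function(coupling, design) {
  if (nrow(coupling) != nrow(design))
    stop("design rows must match the subject count")
  if (qr(design)$rank < ncol(design)) stop("design is rank deficient")
  fit <- ols_tmap(unclass(coupling), design, coef = ncol(design))
  grid <- attr(coupling, "grid")
  base <- if (!is.null(grid)) grid_index(grid) else
    tibble::tibble(voxel = seq_along(fit$t))
  out <- tibble::tibble(base, t = fit$t,
                        p = 2 * stats::pt(-abs(fit$t), fit$df))
  structure(out, df = fit$df, grid = grid,
            class = c("stat_map", class(tibble::tibble())))
}

#' Permutation max-t family-wise error correction
#'
#' Freedman-Lane permutation of reduced-model residuals: the interaction
#' column is dropped, reduced-model fitted values are kept fixed, residual
#' rows are permuted, and the full-model interaction |t| map is recomputed
#' for each permutation. The FWE-corrected p of voxel v is the (+1
#' smoothed) proportion of permutations whose maximum |t| over the mask
#' reaches the observed |t(v)|.
#'
#' @param coupling Subjects x voxels coupling maps.
#' @param design Group design from [build_interaction_design()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Numeric vector of corrected p-values with attribute `max_t`
#'   (the permutation distribution of the maximum |t|).
#' @export
permutation_fwe <- function(coupling, design, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("use at least 100 permutations")
  Y <- unclass(coupling)
  if (qr(design)$rank < ncol(design)) stop("design is rank deficient")
  n <- nrow(Y)
  obs <- abs(ols_tmap(Y, design, coef = ncol(design))$t)
  X0 <- design[, -ncol(design), drop = FALSE]
  fit0 <- X0 %*% solve(crossprod(X0), crossprod(X0, Y))
  R <- Y - fit0
  withr::local_seed(as.integer(seed))
  max_t <- vapply(seq_len(n_perm), function(b) {
    Yb <- fit0 + R[sample.int(n), , drop = FALSE]
    max(abs(ols_tmap(Yb, design, coef = ncol(design))$t))
  }, numeric(1))
  p_fwe <- vapply(obs, function(tv) (1 + sum(max_t >= tv)) / (n_perm + 1),
                  numeric(1))
  attr(p_fwe, "max_t") <- max_t
  p_fwe
}

# 18-connectivity (faces + edges) neighbour offsets
connectivity_offsets <- function(connectivity = 18) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nrm <- rowSums(off^2)
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2,
                 "26" = nrm >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

#' Label suprathreshold clusters
#'
#' Connected components of a significance mask under 18-neighbour
#' (faces + edges) connectivity, discarding components of extent <= `min_k`
#' (the `k > 10` convention). Peaks are located at the maximum |statistic|
#' voxel of each component.
#'
#' @param sig Logical significance mask: a 3-D array or a vector over the
#'   in-mask voxels of `grid`.
#' @param grid The [volume_grid()].
#' @param values Optional per-voxel statistic used for peak localisation
#'   (same layout as `sig`); defaults to all-1.
#' @param min_k Minimum surviving extent is `min_k + 1` voxels.
#' @param connectivity 6, 18 (default) or 26.
#' @return A tibble with one row per surviving cluster: `cluster`, `k`,
#'   peak lattice and mm coordinates, `peak_stat`, and a `voxels`
#'   list-column of linear indices. Empty mask gives an empty table.
#' @export
label_clusters <- function(sig, grid, values = NULL, min_k = 10,
                           connectivity = 18) {
  dims <- grid$dim
  sig_arr <- array(FALSE, dims)
  if (is.array(sig) && length(dim(sig)) == 3) sig_arr[] <- sig else
    sig_arr[which(grid$mask)[sig]] <- TRUE
  val_arr <- array(NA_real_, dims)
  if (!is.null(values)) {
    if (is.array(values) && length(dim(values)) == 3) val_arr[] <- values
    else val_arr[which(grid$mask)] <- values
  } else val_arr[] <- 1
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, dims)
  nclus <- 0L
  comp <- list()
  for (v in which(sig_arr)) {
    if (labels[v] != 0L) next
    nclus <- nclus + 1L
    queue <- v; labels[v] <- nclus; members <- v
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cijk <- arrayInd(cur, dims)
      nb <- sweep(off, 2, as.integer(cijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
        dims[1] * dims[2] * (nb[ok, 3] - 1)
      new <- lin[sig_arr[lin] & labels[lin] == 0L]
      labels[new] <- nclus
      queue <- c(queue, new)
      members <- c(members, new)
    }
    comp[[nclus]] <- sort(members)
  }
  keep <- which(vapply(comp, length, 1L) > min_k)
  rows <- lapply(seq_along(keep), function(ci) {
    vox <- comp[[keep[ci]]]
    pk <- vox[which.max(abs(val_arr[vox]))]
    ijk <- drop(arrayInd(pk, dims))
    mm <- drop(ijk_to_mm(grid, ijk))
    tibble::tibble(cluster = ci, k = length(vox),
                   peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
                   x = mm[1], y = mm[2], z = mm[3],
                   peak_stat = val_arr[pk], voxels = list(vox))
  })
  if (!length(rows))
    return(tibble::tibble(cluster = integer(), k = integer(),
                          peak_i = integer(), peak_j = integer(),
                          peak_k = integer(), x = numeric(), y = numeric(),
                          z = numeric(), peak_stat = numeric(),
                          voxels = list()))
  dplyr::bind_rows(rows)
}

#' Per-subject mean coupling over a cluster
#'
#' @param coupling Subjects x voxels coupling maps (with a `grid`
#'   attribute) and `cluster` given as linear voxel indices, or a bare
#'   matrix with `cluster` as column indices.
#' @param cluster Nonempty voxel set.
#' @return Numeric vector, one mean per subject.
#' @export
extract_cluster_estimates <- function(coupling, cluster) {
  if (!length(cluster)) stop("empty cluster")
  grid <- attr(coupling, "grid")
  cols <- if (!is.null(grid)) mask_columns(grid, cluster) else cluster
  rowMeans(unclass(coupling)[, cols, drop = FALSE])
}

#' Per-group trait-coupling slope report
#'
#' Pearson correlation between the trait and the extracted cluster coupling
#' within each genotype group, with Bonferroni correction over the tested
#' SNP-allele families and a flag for sign opposition between groups.
#'
#' @param estimates Per-subject mean coupling (from
#'   [extract_cluster_estimates()]).
#' @param traits Trait scores.
#' @param carriers 0/1 carrier indicator.
#' @param m Bonferroni multiplier (default 8 = 4 SNPs x 2 alleles).
#' @param one_tailed Report additionally the halved (one-tailed) corrected
#'   p; never substituted silently.
#' @return An `interaction_report` tibble, one row per group: `group`, `n`,
#'   `r`, `p`, `p_corrected`, `slope_sign`; attribute `sign_opposition`.
#' @export
group_slope_report <- function(estimates, traits, carriers, m = 8,
                               one_tailed = FALSE) {
  stopifnot(length(estimates) == length(traits),
            length(traits) == length(carriers))
  out <- lapply(c(noncarrier = 0, carrier = 1), function(gv) {
    sel <- carriers == gv
    if (sum(sel) < 3) stop("each group needs at least 3 subjects")
    if (stats::sd(estimates[sel]) == 0)
      stop("zero-variance coupling estimates")
    ct <- pearson_test(traits[sel], estimates[sel])
    tibble::tibble(n = sum(sel), r = ct$r, p = ct$p,
                   p_corrected = bonferroni(ct$p, m),
                   slope_sign = sign(ct$r))
  })
  rep_tbl <- dplyr::bind_cols(
    tibble::tibble(group = names(out)), dplyr::bind_rows(out))
  if (one_tailed)
    rep_tbl$p_corrected_one_tailed <- pmin(1, m * rep_tbl$p / 2)
  structure(rep_tbl,
            sign_opposition = prod(rep_tbl$slope_sign) < 0,
            class = c("interaction_report", class(tibble::tibble())))
}

#' Group genotype-by-trait interaction analysis
#'
#' End-to-end group stage: builds the moderation design for one SNP's
#' carrier grouping, computes the voxelwise interaction t map, corrects it
#' by permutation max-|t| FWE, labels suprathreshold clusters (extent
#' `k > min_k`, Bonferroni x `m_emotions` on peak p), and reports per-group
#' trait-coupling slopes for every surviving cluster.
#'
#' @param coupling A `coupling_maps` object.
#' @param phenotypes Phenotype tibble containing `asq_total` and
#'   `carrier_<snp>`.
#' @param snp SNP defining the carrier grouping.
#' @param alpha Peak-level FWE threshold (default 0.05).
#' @param min_k Cluster-extent threshold (`k > min_k`).
#' @param m_emotions Bonferroni multiplier for the emotion family
#'   (default 3).
#' @param m_snps Bonferroni multiplier for the slope report (default 8).
#' @param n_perm,seed Permutation settings.
#' @return A `group_interaction` list: `stat_map` (with `p_fwe` column),
#'   `clusters` (Table-1-style tibble with `k`, peak `t`, `p_fwe`,
#'   `p_corrected`, mm coordinates), `reports` (one
#'   [group_slope_report()] per cluster), `design`, `snp`.
#' @export
group_interaction <- function(coupling, phenotypes, snp = "rs2254298",
                              alpha = 0.05, min_k = 10, m_emotions = 3,
                              m_snps = 8, n_perm = 1000, seed = 1L) {
  carriers <- phenotypes[[paste0("carrier_", snp)]]
  if (is.null(carriers)) stop("no carrier column for ", snp)
  traits <- phenotypes$asq_total
  design <- build_interaction_design(carriers, traits)
  sm <- interaction_tmap(coupling, design)
  p_fwe <- permutation_fwe(coupling, design, n_perm = n_perm, seed = seed)
  sm$p_fwe <- as.numeric(p_fwe)
  grid <- attr(coupling, "grid")
  clusters <- label_clusters(sm$p_fwe < alpha, grid, values = sm$t,
                             min_k = min_k)
  if (nrow(clusters)) {
    peak_lin <- clusters$peak_i + grid$dim[1] * (clusters$peak_j - 1) +
      grid$dim[1] * grid$dim[2] * (clusters$peak_k - 1)
    clusters$p_fwe <- sm$p_fwe[mask_columns(grid, peak_lin)]
    clusters$p_corrected <- pmin(1, m_emotions * clusters$p_fwe)
  } else {
    clusters$p_fwe <- numeric(0)
    clusters$p_corrected <- numeric(0)
  }
  reports <- lapply(clusters$voxels, function(vox)
    group_slope_report(extract_cluster_estimates(coupling, vox),
                       traits, carriers, m = m_snps))
  structure(list(stat_map = sm, clusters = clusters, reports = reports,
                 design = design, snp = snp, alpha = alpha, min_k = min_k,
                 max_t = attr(p_fwe, "max_t")),
            class = "group_interaction")
}

#' @export
print.group_interaction <- function(x, ...) {
  cat(sprintf("<group_interaction> SNP %s: %d surviving cluster(s) at peak p_FWE < %g, k > %d\n",
              x$snp, nrow(x$clusters), x$alpha, x$min_k))
  if (nrow(x$clusters))
    print(dplyr::select(x$clusters, -"voxels"))
  invisible(x)
}
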
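#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prediction map
#'
#' @param x A `prediction_map` from [searchlight_predict()].
#' @param ... Unused.
#' @return A plain tibble of per-voxel results.
#' @exportS3Method
tidy.prediction_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a prediction map
#'
#' @param x A `prediction_map`.
#' @param ... Unused.
#' @return A tibble with the contrast, voxel counts, FDR settings, critical
#'   p, number of significant voxels and the peak prediction-outcome r.
#' @exportS3Method
glance.prediction_map <- function(x, ...) {
  spec <- attr(x, "spec")
  ok <- !is.na(x$r)
  tibble::tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_subjects = attr(x, "n_subjects"),
    n_voxels = nrow(x), n_tested = sum(ok),
    radius_vox = spec$radius_vox, n_folds = spec$n_folds,
    fdr_q = spec$fdr_q, critical_p = attr(x, "critical_p"),
    n_significant = sum(x$fdr_sig),
    peak_r = if (any(ok)) max(x$r[ok]) else NA_real_
  )
}

#' Tidy contrast or coupling maps
#'
#' @param x A `contrast_maps` or `coupling_maps` object.
#' @param ... Unused.
#' @return Long tibble: `subject_id`, `voxel`, `value`.
#' @exportS3Method
tidy.contrast_maps <- function(x, ...) {
  grid <- attr(x, "grid")
  vox <- which(grid$mask)
  tibble::tibble(
    subject_id = rep(attr(x, "subject_id"), each = length(vox)),
    voxel = rep(vox, times = nrow(x)),
    value = as.vector(t(unclass(x)))
  )
}

#' @rdname tidy.contrast_maps
#' @exportS3Method
tidy.coupling_maps <- tidy.contrast_maps

#' Tidy an ANOVA result
#'
#' @param x An `anova_result` from [rm_anova()].
#' @param ... Unused.
#' @return One-row tibble with `F`, dfs, `p`, `eta_sq_partial`.
#' @exportS3Method
tidy.anova_result <- function(x, ...) {
  tibble::tibble(F = x$F, df1 = x$df[1], df2 = x$df[2], p = x$p,
                 eta_sq_partial = x$eta_sq_partial)
}

#' Tidy a group interaction analysis
#'
#' @param x A `group_interaction` from [group_interaction()].
#' @param ... Unused.
#' @return The cluster table (Region column left blank; peak mm
#'   coordinates, extent k, peak t, p_FWE, Bonferroni-corrected p), one row
#'   per surviving cluster.
#' @exportS3Method
tidy.group_interaction <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(region = rep("", nrow(cl)), k = cl$k,
                 t = cl$peak_stat, p_fwe = cl$p_fwe,
                 p_corrected = cl$p_corrected,
                 x = cl$x, y = cl$y, z = cl$z)
}

#' One-row summary of a group interaction analysis
#'
#' @param x A `group_interaction`.
#' @param ... Unused.
#' @return Tibble with the SNP, thresholds, cluster count and smallest
#'   corrected peak p.
#' @exportS3Method
glance.group_interaction <- function(x, ...) {
  tibble::tibble(
    snp = x$snp, alpha = x$alpha, min_k = x$min_k,
    n_clusters = nrow(x$clusters),
    min_p_corrected = if (nrow(x$clusters))
      min(x$clusters$p_corrected) else NA_real_
  )
}
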
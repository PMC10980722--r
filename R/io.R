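#' Embed an in-mask vector into a 3-D array
#'
#' @param values Numeric vector over the in-mask voxels of `grid`.
#' @param grid The [volume_grid()].
#' @param fill Value outside the mask (default `NA`).
#' @return 3-D array of dimension `grid$dim`.
#' @export
unmask <- function(values, grid, fill = NA_real_) {
  stopifnot(length(values) == sum(grid$mask))
  arr <- array(fill, grid$dim)
  arr[grid$mask] <- values
  arr
}

# build a NIfTI image with the grid's diagonal RAS affine
as_nifti_image <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  aff <- diag(4)
  aff[cbind(1:3, 1:3)] <- grid$voxel_size_mm
  aff[1:3, 4] <- grid$origin
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write a map or volume as NIfTI-1
#'
#' @param x A per-voxel vector over in-mask voxels, a 3-D array, or a
#'   scans x voxels matrix (written as a 4-D series).
#' @param grid The [volume_grid()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, grid, path) {
  if (is.matrix(x)) {
    arr <- array(NA_real_, c(grid$dim, nrow(x)))
    for (s in seq_len(nrow(x))) {
      a3 <- array(0, grid$dim); a3[grid$mask] <- x[s, ]
      arr[, , , s] <- a3
    }
  } else if (is.array(x) && length(dim(x)) >= 3) {
    arr <- x
  } else {
    arr <- unmask(x, grid)
  }
  RNifti::writeNifti(as_nifti_image(arr, grid), path)
  invisible(path)
}

#' Read a NIfTI map back onto a grid
#'
#' @param path NIfTI file path.
#' @param grid Optional [volume_grid()]; when supplied, 3-D images are
#'   returned as in-mask vectors and 4-D images as scans x voxels matrices.
#' @return Vector/matrix (with `grid`) or the raw array.
#' @export
read_nifti_map <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (is.null(grid)) return(arr)
  stopifnot(all(dim(arr)[1:3] == grid$dim))
  if (length(dim(arr)) == 3) return(arr[grid$mask])
  t(apply(arr, 4, function(v) v[grid$mask]))
}

#' Write a synthetic cohort to a BIDS-like directory
#'
#' Writes `participants.tsv` (subject id, ASQ total, genotype and carrier
#' columns, sex, age), per-run `events.tsv` files (onset, duration,
#' trial_type, stimulus_id), per-subject 4-D BOLD NIfTI files and motion
#' TSVs, the grey-matter mask, and `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param subjects Which subjects' BOLD to materialize (default all).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, subjects = NULL) {
  spec <- cohort$spec
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cohort$phenotypes
  utils::write.table(
    dplyr::select(ph, -dplyr::any_of(c("items", "latent_trait"))),
    file.path(dir, "participants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (r in sort(unique(cohort$schedule$run))) {
    ev <- cohort$schedule[cohort$schedule$run == r, ]
    utils::write.table(
      data.frame(onset = ev$onset, duration = ev$duration,
                 trial_type = ev$condition, stimulus_id = ev$stimulus_id),
      file.path(dir, sprintf("task-faces_run-%02d_events.tsv", r)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_nifti_map(array(as.numeric(spec$grid$mask), spec$grid$dim),
                  spec$grid, file.path(dir, "mask.nii.gz"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(trait_z = gt$trait_z, pattern_voxels = gt$pattern_voxels,
         pattern_weights = gt$pattern_weights,
         coupling_gains = gt$coupling_gains,
         group_slopes = gt$group_slopes),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  subjects <- subjects %||% seq_len(spec$n_subjects)
  for (i in subjects) {
    sub <- simulate_subject_bold(cohort, i)
    n_scans <- spec$volumes_per_run
    for (r in seq_len(spec$n_runs)) {
      rows <- (r - 1) * n_scans + seq_len(n_scans)
      write_nifti_map(sub$bold[rows, , drop = FALSE], spec$grid,
                      file.path(dir, sprintf("%s_run-%02d_bold.nii.gz",
                                             ph$subject_id[i], r)))
    }
    utils::write.table(
      as.data.frame(sub$motion),
      file.path(dir, sprintf("%s_motion.tsv", ph$subject_id[i])),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
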
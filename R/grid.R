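#' Define a volume grid
#'
#' A `volume_grid` is the spatial frame shared by every map in the pipeline:
#' a 3-D voxel lattice, a diagonal RAS voxel-to-mm affine, and a boolean
#' grey-matter mask restricting all voxelwise analyses.
#'
#' @param dim Integer vector of length 3, grid dimensions in voxels.
#' @param voxel_size_mm Voxel edge length(s) in mm; length 1 or 3.
#' @param origin mm coordinates of the centre of voxel (1, 1, 1).
#' @param mask Logical array of dimension `dim`, or `NULL` for an all-`TRUE`
#'   mask.
#'
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(16, 16, 16), voxel_size_mm = 3)
#' sum(g$mask)
volume_grid <- function(dim, voxel_size_mm = 3, origin = NULL, mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (is.null(origin)) origin <- -(dim - 1) / 2 * voxel_size_mm
  if (is.null(mask)) {
    mask <- array(TRUE, dim)
  } else {
    mask <- array(as.logical(mask), dim)
    if (anyNA(mask)) stop("mask must not contain NA")
  }
  if (!sum(mask)) stop("mask is empty")
  structure(
    list(dim = dim, voxel_size_mm = voxel_size_mm, origin = origin,
         mask = mask),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %s mm, %d in mask\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Tabulate in-mask voxels
#'
#' @param grid A [volume_grid()].
#' @return A tibble with one row per in-mask voxel: linear index `voxel`,
#'   lattice coordinates `i`, `j`, `k`, and mm coordinates `x`, `y`, `z`.
#' @export
grid_index <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  vox <- which(grid$mask)
  ijk <- arrayInd(vox, grid$dim)
  mm <- ijk_to_mm(grid, ijk)
  tibble::tibble(
    voxel = vox,
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = mm[, 1], y = mm[, 2], z = mm[, 3]
  )
}

#' Convert lattice coordinates to mm
#'
#' @param grid A [volume_grid()].
#' @param ijk Matrix (or length-3 vector) of 1-based voxel coordinates.
#' @return Matrix of mm coordinates under the grid's diagonal RAS affine.
#' @export
ijk_to_mm <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, grid$voxel_size_mm, `*`), 2, grid$origin, `+`)
}

#' Voxel indices inside a lattice ball
#'
#' Enumerates grid voxels whose lattice distance from `center_ijk` is at most
#' `radius_vox` (the same ball the searchlight uses). Indices falling outside
#' the grid are dropped; the mask is not applied.
#'
#' @param grid A [volume_grid()].
#' @param center_ijk 1-based voxel coordinates of the ball centre.
#' @param radius_vox Ball radius in voxel units.
#' @return Sorted vector of linear voxel indices.
#' @export
voxel_ball <- function(grid, center_ijk, radius_vox) {
  off <- sphere_offsets(radius_vox)
  ijk <- sweep(off, 2, as.integer(center_ijk), `+`)
  keep <- ijk[, 1] >= 1 & ijk[, 1] <= grid$dim[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= grid$dim[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= grid$dim[3]
  ijk <- ijk[keep, , drop = FALSE]
  sort(ijk[, 1] + grid$dim[1] * (ijk[, 2] - 1) +
         grid$dim[1] * grid$dim[2] * (ijk[, 3] - 1))
}

#' Voxels within an mm-radius sphere
#'
#' In-mask voxels whose centre lies within `radius_mm` of `center_mm`
#' (centre-in-sphere rule, used for seed placement).
#'
#' @param grid A [volume_grid()].
#' @param center_mm Sphere centre in mm.
#' @param radius_mm Sphere radius in mm.
#' @return Vector of linear voxel indices (in-mask only).
#' @export
mm_sphere <- function(grid, center_mm, radius_mm) {
  stopifnot(radius_mm > 0)
  idx <- grid_index(grid)
  d2 <- (idx$x - center_mm[1])^2 + (idx$y - center_mm[2])^2 +
    (idx$z - center_mm[3])^2
  idx$voxel[d2 <= radius_mm^2]
}

# map linear voxel indices to columns of an in-mask data matrix
mask_columns <- function(grid, voxels) {
  lut <- integer(prod(grid$dim))
  lut[which(grid$mask)] <- seq_len(sum(grid$mask))
  cols <- lut[voxels]
  cols[cols > 0L]
}
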
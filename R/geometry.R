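# R-level wrappers around the compiled voxel-geometry kernels.

#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance (mm, spacing-aware) from every voxel centre to
#' the nearest `TRUE` voxel centre. Optionally also returns, for every
#' voxel, the (1-based linear) index of a nearest `TRUE` voxel.
#'
#' @param mask logical 3D array.
#' @param grid a [VoxelGrid] (only its spacing is used; the transform is
#'   computed on the voxel lattice).
#' @param feature also return nearest-feature indices.
#' @return distance array, or `list(distance, feature)` when
#'   `feature = TRUE`.
#' @export
distanceTransform <- function(mask, grid, feature = FALSE) {
  g <- .gridOf(grid)
  stopifnot(all(dim(mask) == g@dim))
  res <- .edt3d_cpp(as.logical(mask), g@dim, spacing(g), feature)
  if (feature) res else res$distance
}

#' Dilate a binary mask by a metric radius
#'
#' A voxel is set iff its centre lies within `radiusMm` (Euclidean, world
#' mm, anisotropy-aware) of an input voxel centre; radius 0 is the identity.
#' Implemented by thresholding the exact distance transform, which gives
#' exact mm semantics on anisotropic grids (unlike iterated structuring
#' elements).
#'
#' @param mask logical 3D array.
#' @param grid the [VoxelGrid].
#' @param radiusMm dilation radius in mm (>= 0).
#' @return logical 3D array.
#' @export
dilateMask <- function(mask, grid, radiusMm) {
  if (radiusMm < 0) stop("dilation radius must be >= 0", call. = FALSE)
  if (!any(mask) || radiusMm == 0) return(mask)
  d <- distanceTransform(mask, grid)
  array(d <= radiusMm + 1e-9, dim(mask))
}

# trilinear interpolation of a numeric array at world-mm points
interpWorld <- function(vol, grid, pointsMm) {
  g <- .gridOf(grid)
  p <- if (is.null(dim(pointsMm))) matrix(pointsMm, 1) else pointsMm
  .interp3_cpp(as.numeric(vol), g@dim, worldToVoxel(g, p))
}

# nearest-voxel mask membership at world-mm points (FALSE outside the grid)
pointsInMask <- function(mask, grid, pointsMm) {
  g <- .gridOf(grid)
  p <- if (is.null(dim(pointsMm))) matrix(pointsMm, 1) else pointsMm
  v <- round(worldToVoxel(g, p)) + 1
  ok <- v[, 1] >= 1 & v[, 2] >= 1 & v[, 3] >= 1 &
    v[, 1] <= g@dim[1] & v[, 2] <= g@dim[2] & v[, 3] <= g@dim[3]
  out <- logical(nrow(p))
  if (any(ok)) {
    lin <- (v[ok, 3] - 1) * g@dim[1] * g@dim[2] + (v[ok, 2] - 1) * g@dim[1] +
      v[ok, 1]
    out[ok] <- as.logical(mask)[lin]
  }
  out
}

# world-space point inside the interpolation hull of the grid?
pointsInGrid <- function(grid, pointsMm) {
  g <- .gridOf(grid)
  p <- if (is.null(dim(pointsMm))) matrix(pointsMm, 1) else pointsMm
  v <- worldToVoxel(g, p)
  v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
    v[, 1] <= g@dim[1] - 1 & v[, 2] <= g@dim[2] - 1 & v[, 3] <= g@dim[3] - 1
}

# number of 26-connected components
nComponents26 <- function(mask) {
  .n_components26_cpp(as.logical(mask), dim(mask))
}
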
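#' Median denoising of a volume
#'
#' Each voxel becomes the median of its `(2r+1)^3` neighbourhood (edge
#' replication at the borders). This attenuates the unevenly distributed
#' bright voxels that a brachytherapy applicator induces in HDR-BT CT while
#' preserving edges; the default radius of 1 (a 3x3x3 window) removes
#' isolated impulses.
#'
#' @param img an [image3d].
#' @param radius non-negative integer radius, scalar or per-axis 3-vector.
#' @return denoised [image3d] on the same geometry.
#' @export
median_denoise <- function(img, radius = 1) {
  stopifnot(is_image3d(img))
  radius <- as.integer(rep_len(radius, 3))
  if (any(radius < 0)) stop("median radius must be >= 0 per axis")
  if (all(radius == 0L)) return(img)
  vox <- c_median_filter(as.numeric(img$voxels), dim(img$voxels), radius)
  image3d(array(vox, dim(img$voxels)), img$origin, img$spacing, img$direction)
}

#' Resample a volume onto a reference grid
#'
#' The source is interpolated at the world position of every reference voxel;
#' positions outside the source footprint receive `pad_value`.
#'
#' @param src source [image3d].
#' @param ref reference [image3d] providing the output grid.
#' @param interp `nearest`, `linear`, `c1spline` (Catmull-Rom),
#'   `cubic_bspline` (smoothing B-spline kernel) or `sinc` (Lanczos-3).
#' @param pad_value intensity used outside the source footprint; defaults to
#'   the source minimum.
#' @return an [image3d] on the reference grid.
#' @export
resample_to_reference <- function(src, ref, interp = "linear", pad_value = NULL) {
  stopifnot(is_image3d(src), is_image3d(ref))
  vals <- sample_image(src, grid_world_points(ref), interp, pad_value)
  image3d(array(vals, dim(ref$voxels)), ref$origin, ref$spacing, ref$direction)
}

#' Reorient a volume to match a reference orientation
#'
#' Regrids the source onto a grid sharing the reference direction matrix
#' while leaving the world position of the tissue unchanged. When the two
#' direction matrices are related by a signed axis permutation the new grid
#' nodes coincide exactly with source voxel centres and the operation is a
#' lossless shuffle; the general oblique case is not supported by the
#' registration engine and is refused.
#'
#' @param src source [image3d].
#' @param ref [image3d] supplying the target orientation.
#' @param interp interpolator passed to [resample_to_reference()].
#' @return an [image3d] with `direction` equal to the reference's.
#' @export
reorient_to <- function(src, ref, interp = "nearest") {
  stopifnot(is_image3d(src), is_image3d(ref))
  if (max(abs(src$direction - ref$direction)) < 1e-9) return(src)
  rel <- t(ref$direction) %*% src$direction
  if (max(abs(abs(rel) - round(abs(rel)))) > 1e-6)
    stop("reorientation requires directions related by a signed axis permutation")
  # permuted spacing: extent of one source step along each new axis
  sp_new <- as.numeric(abs(rel) %*% src$spacing)
  b <- image_bounds(src)
  # corner of the bounding box that is minimal along each new axis
  corners <- as.matrix(expand.grid(c(b$lower[1], b$upper[1]),
                                   c(b$lower[2], b$upper[2]),
                                   c(b$lower[3], b$upper[3])))
  proj <- corners %*% ref$direction
  origin_new <- as.numeric(ref$direction %*% apply(proj, 2, min))
  d_new <- as.integer(round(abs(rel) %*% (dim(src$voxels) - 1))) + 1L
  grid <- image3d(array(0, d_new), origin = origin_new, spacing = sp_new,
                  direction = ref$direction)
  resample_to_reference(src, grid, interp = interp)
}

# Gaussian smoothing in voxel units (sigma per axis), edge replication.
gaussian_smooth <- function(img, sigma = 1) {
  sigma <- rep_len(as.numeric(sigma), 3)
  vox <- c_gauss_smooth(as.numeric(img$voxels), dim(img$voxels), sigma)
  image3d(array(vox, dim(img$voxels)), img$origin, img$spacing, img$direction)
}

# One pyramid level: Gaussian smoothing (sigma = 1 voxel) then x2 decimation,
# keeping voxel (0,0,0) so the origin is unchanged and spacing doubles.
downsample2 <- function(img) {
  sm <- gaussian_smooth(img, 1)
  d <- dim(img$voxels)
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2); iz <- seq(1, d[3], by = 2)
  image3d(sm$voxels[ix, iy, iz, drop = FALSE], img$origin, img$spacing * 2,
          img$direction)
}

# levels[[1]] is the finest (original) image.
build_pyramid <- function(img, levels) {
  out <- vector("list", levels)
  out[[1]] <- img
  if (levels > 1)
    for (l in 2:levels) out[[l]] <- downsample2(out[[l - 1]])
  out
}
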
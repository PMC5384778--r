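#' 3D scalar volume with world-space geometry
#'
#' The basic container of the package: a rank-3 voxel array together with its
#' world geometry (origin, spacing and an orthonormal direction matrix), all
#' expressed in the DICOM patient frame (LPS, mm). Continuous voxel indices
#' are 0-based and refer to voxel centres: index `(0,0,0)` sits exactly at
#' `origin`.
#'
#' @param voxels numeric 3D array of intensities (Hounsfield-like, arbitrary
#'   units).
#' @param origin world position (mm, LPS) of the centre of voxel `(0,0,0)`.
#' @param spacing voxel edge lengths in mm, strictly positive.
#' @param direction 3x3 orthonormal matrix whose columns are the world
#'   directions of the voxel axes.
#' @param frame_tag label of the world convention; only `"LPS"` is used
#'   internally.
#' @return an object of class `image3d`.
#' @export
image3d <- function(voxels, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                    direction = diag(3), frame_tag = "LPS") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("voxels must be a non-empty rank-3 array")
  # canonical double array without foreign attributes (e.g. from readers)
  voxels <- array(as.double(voxels), dim(voxels))
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("origin and spacing must be length-3")
  if (any(!is.finite(origin)) || any(!is.finite(spacing)))
    stop("origin and spacing must be finite")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal (to 1e-6)")
  structure(list(voxels = voxels, origin = origin, spacing = spacing,
                 direction = direction, frame_tag = frame_tag),
            class = "image3d")
}

is_image3d <- function(x) inherits(x, "image3d")

#' @export
print.image3d <- function(x, ...) {
  cat("image3d:", paste(dim(x$voxels), collapse = " x "), "voxels\n")
  cat("  origin  (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  cat("  spacing (mm):", paste(signif(x$spacing, 6), collapse = ", "), "\n")
  cat("  frame:", x$frame_tag,
      if (max(abs(x$direction - diag(3))) < 1e-9) "(axis-aligned)" else "(oblique)", "\n")
  cat("  intensity range:", paste(signif(range(x$voxels), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$voxels)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' Convert between world coordinates and continuous voxel indices
#'
#' Continuous (unrounded) 0-based indices; points outside the grid are legal
#' and simply map to indices outside `[0, dim-1]`.
#'
#' @param img an [image3d].
#' @param p numeric 3-vector (mm) or N x 3 matrix of world points.
#' @return matrix (N x 3) of continuous indices, or world points for the
#'   inverse.
#' @export
world_to_voxel <- function(img, p) {
  p <- to_points_matrix(p)
  idx <- (p - matrix(img$origin, nrow(p), 3, byrow = TRUE)) %*% img$direction
  sweep(idx, 2, img$spacing, "/")
}

#' @rdname world_to_voxel
#' @param idx continuous voxel indices (3-vector or N x 3).
#' @export
voxel_to_world <- function(img, idx) {
  idx <- to_points_matrix(idx)
  p <- sweep(idx, 2, img$spacing, "*") %*% t(img$direction)
  p + matrix(img$origin, nrow(p), 3, byrow = TRUE)
}

#' @rdname world_to_voxel
#' @export
point_in_image <- function(img, p) {
  idx <- world_to_voxel(img, p)
  d <- dim(img$voxels)
  idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
}

to_points_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns")
    storage.mode(p) <- "double"
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 coordinates")
    matrix(as.numeric(p), 1, 3)
  }
}

# World coordinates of every voxel centre, x-fastest, as an N x 3 matrix.
grid_world_points <- function(img) {
  d <- dim(img$voxels)
  idx <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(img, idx)
}

# World-space axis-aligned bounding box of the voxel-centre hull.
image_bounds <- function(img) {
  d <- dim(img$voxels)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  w <- voxel_to_world(img, corners)
  list(lower = apply(w, 2, min), upper = apply(w, 2, max))
}

#' Axis-aligned region of interest in world coordinates
#'
#' @param lower,upper world-space corners (mm), `lower < upper` componentwise.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("roi corners must be length-3")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("roi corners must be finite")
  if (any(lower >= upper)) stop("roi lower corner must be < upper componentwise")
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

roi_contains <- function(roi, p) {
  p <- to_points_matrix(p)
  p[, 1] >= roi$lower[1] & p[, 1] <= roi$upper[1] &
    p[, 2] >= roi$lower[2] & p[, 2] <= roi$upper[2] &
    p[, 3] >= roi$lower[3] & p[, 3] <= roi$upper[3]
}

roi_dilate <- function(roi, by) {
  by <- rep_len(as.numeric(by), 3)
  roi_box(roi$lower - by, roi$upper + by)
}
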
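#' Spatial transform family
#'
#' The transform model is additive: a composite transform maps a point `x`
#' in the target (reference) frame to `T_global(x) + sum_k u_k(x)` where
#' `T_global` is rigid, affine or the identity and each `u_k` is the
#' displacement field of a B-spline free-form deformation (FFD) lattice
#' evaluated at target-frame coordinates. Warping uses the pull-back
#' convention: the composite maps reference-frame points into the source
#' frame, and the warped image samples the source there.
#'
#' @param rotation 3x3 proper rotation matrix (`det = +1`).
#' @param translation 3-vector, mm.
#' @return transform objects of class `rigid_transform`, `affine_transform`,
#'   `ffd_lattice` or `composite_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be a proper rotation matrix (orthonormal, det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = c("rigid_transform", "linear_transform"))
}

#' @rdname rigid_transform
#' @param matrix invertible 3x3 linear part (may include scale and shear).
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  if (abs(det(matrix)) <= 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, translation = translation),
            class = c("affine_transform", "linear_transform"))
}

linear_matrix <- function(t) {
  if (inherits(t, "rigid_transform")) t$rotation else t$matrix
}

#' B-spline free-form deformation lattice
#'
#' A uniform lattice of control points carrying world-space displacement
#' coefficients (mm). The displacement at a point is the cubic B-spline
#' tensor-product sum over its 4x4x4 control neighbourhood; control node
#' `(i,j,k)` (0-based) sits at `grid_origin + (i,j,k) * spacing`. Points
#' without a full neighbourhood get zero displacement. When `roi` is set,
#' `free_mask` marks the movable control points: a node is free iff its
#' world position lies inside the ROI dilated by one control spacing (nodes
#' just outside the box still influence interior voxels). In the default
#' smooth mode the spline is evaluated everywhere, so displacement decays
#' continuously to exactly zero beyond two spacings from the free nodes;
#' `strict_piecewise = TRUE` instead forces the identity outside the ROI box,
#' reproducing the literal piecewise definition at the cost of a boundary
#' discontinuity.
#'
#' @param grid_origin world position (mm) of control node (0,0,0).
#' @param spacing control-point spacing per axis, mm.
#' @param shape integer 3-vector of control counts, each >= 4.
#' @param coefficients array `(nx, ny, nz, 3)` of displacements (mm), or NULL
#'   for all-zero.
#' @param roi optional [roi_box] restricting which control points may move.
#' @param free_mask optional logical array `(nx, ny, nz)`; derived from `roi`
#'   when omitted, all-TRUE when neither is given.
#' @param strict_piecewise logical; see above.
#' @export
ffd_lattice <- function(grid_origin, spacing, shape, coefficients = NULL,
                        roi = NULL, free_mask = NULL, strict_piecewise = FALSE) {
  grid_origin <- as.numeric(grid_origin)
  spacing <- rep_len(as.numeric(spacing), 3)
  shape <- as.integer(rep_len(shape, 3))
  if (any(shape < 4L)) stop("FFD lattice needs at least 4 control points per axis")
  if (any(spacing <= 0)) stop("control spacing must be positive")
  if (is.null(coefficients)) coefficients <- array(0, c(shape, 3))
  coefficients <- array(as.numeric(coefficients), c(shape, 3))
  if (any(!is.finite(coefficients))) stop("FFD coefficients must be finite")
  if (is.null(free_mask)) {
    if (is.null(roi)) {
      free_mask <- array(TRUE, shape)
    } else {
      dil <- roi_dilate(roi, spacing)
      nodes <- lattice_node_world(grid_origin, spacing, shape)
      free_mask <- array(roi_contains(dil, nodes), shape)
    }
  }
  free_mask <- array(as.logical(free_mask), shape)
  structure(list(grid_origin = grid_origin, spacing = spacing, shape = shape,
                 coefficients = coefficients, free_mask = free_mask,
                 roi = roi, strict_piecewise = isTRUE(strict_piecewise)),
            class = "ffd_lattice")
}

lattice_node_world <- function(origin, spacing, shape) {
  idx <- as.matrix(expand.grid(seq_len(shape[1]) - 1, seq_len(shape[2]) - 1,
                               seq_len(shape[3]) - 1))
  sweep(sweep(idx, 2, spacing, "*"), 2, origin, "+")
}

#' Build a lattice covering an image domain
#'
#' The lattice covers the target domain plus a one-spacing margin on each
#' side, so every point of the domain has a full 4x4x4 control neighbourhood.
#'
#' @param img the [image3d] whose world bounding box must be covered.
#' @param spacing control spacing (mm, scalar or 3-vector).
#' @inheritParams ffd_lattice
#' @export
ffd_lattice_covering <- function(img, spacing, roi = NULL,
                                 strict_piecewise = FALSE) {
  spacing <- rep_len(as.numeric(spacing), 3)
  b <- image_bounds(img)
  origin <- b$lower - spacing
  shape <- pmax(4L, as.integer(ceiling((b$upper - b$lower) / spacing - 1e-9)) + 4L)
  ffd_lattice(origin, spacing, shape, roi = roi,
              strict_piecewise = strict_piecewise)
}

#' Uniform cubic B-spline basis functions
#'
#' The four polynomial pieces `B_0..B_3` that weight a 4-point control
#' neighbourhood; they form a partition of unity on `[0, 1)`.
#'
#' @param l basis index, 0..3.
#' @param t fraction in `[0, 1)` (vectorized).
#' @return basis weights, same length as `t`.
#' @export
bspline_basis <- function(l, t) {
  if (length(l) != 1L || !(l %in% 0:3)) stop("basis index l must be one of 0,1,2,3")
  if (any(t < 0 | t >= 1)) stop("t must lie in [0, 1)")
  switch(as.character(l),
         "0" = (1 - t)^3 / 6,
         "1" = (3 * t^3 - 6 * t^2 + 4) / 6,
         "2" = (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
         "3" = t^3 / 6)
}

#' Evaluate the displacement field of an FFD lattice
#'
#' @param lat an [ffd_lattice].
#' @param p world point(s), 3-vector or N x 3 matrix (mm).
#' @return N x 3 matrix of displacements (mm).
#' @export
ffd_displacement <- function(lat, p) {
  p <- to_points_matrix(p)
  has_roi <- !is.null(lat$roi)
  c_ffd_disp(as.numeric(lat$coefficients), lat$shape, lat$grid_origin,
             lat$spacing, p, lat$strict_piecewise, has_roi,
             if (has_roi) lat$roi$lower else c(0, 0, 0),
             if (has_roi) lat$roi$upper else c(0, 0, 0))
}

#' Composite transform: global part plus summed local FFD displacements
#'
#' @param global a [rigid_transform], [affine_transform] or NULL (identity).
#' @param locals list of [ffd_lattice] objects; their displacement fields are
#'   summed (the additive local model).
#' @export
composite_transform <- function(global = NULL, locals = list()) {
  if (!is.null(global) && !inherits(global, "linear_transform"))
    stop("global part must be rigid, affine or NULL")
  if (inherits(locals, "ffd_lattice")) locals <- list(locals)
  if (!all(vapply(locals, inherits, TRUE, "ffd_lattice")))
    stop("locals must be ffd_lattice objects")
  structure(list(global = global, locals = locals), class = "composite_transform")
}

as_composite <- function(t) {
  if (inherits(t, "composite_transform")) t
  else if (inherits(t, "linear_transform")) composite_transform(global = t)
  else if (inherits(t, "ffd_lattice")) composite_transform(locals = list(t))
  else if (is.null(t)) composite_transform()
  else stop("cannot interpret object as a transform")
}

#' Apply a transform to points
#'
#' @param t any transform of the family (or NULL for the identity).
#' @param p world point(s), 3-vector or N x 3 matrix (mm).
#' @return N x 3 matrix of mapped points (mm).
#' @export
apply_transform_point <- function(t, p) {
  p <- to_points_matrix(p)
  t <- as_composite(t)
  out <- if (is.null(t$global)) p
  else p %*% t(linear_matrix(t$global)) +
    matrix(t$global$translation, nrow(p), 3, byrow = TRUE)
  for (lat in t$locals) out <- out + ffd_displacement(lat, p)
  out
}

interp_code <- function(interp) {
  code <- match(interp, c("nearest", "linear", "c1spline", "cubic_bspline", "sinc"))
  if (is.na(code)) stop("unknown interpolation '", interp,
                        "' (use nearest|linear|c1spline|cubic_bspline|sinc)")
  code - 1L
}

sample_image <- function(img, world_pts, interp = "linear", pad_value = NULL) {
  if (is.null(pad_value)) pad_value <- min(img$voxels)
  idx <- world_to_voxel(img, world_pts)
  c_interp(as.numeric(img$voxels), dim(img$voxels), idx,
           interp_code(interp), pad_value)
}

#' Warp an image through a transform (pull-back)
#'
#' Every voxel of the reference grid is mapped through `t` into the source
#' frame and the source image is interpolated there:
#' `out(i) = interp(src, T(world(i)))`.
#'
#' @param src source [image3d].
#' @param t transform mapping reference-frame points into source space.
#' @param ref [image3d] defining the output grid.
#' @param interp one of `nearest`, `linear`, `c1spline`, `cubic_bspline`,
#'   `sinc`.
#' @param pad_value intensity for points outside the source footprint
#'   (default: source minimum).
#' @return an [image3d] on the reference grid.
#' @export
warp_image <- function(src, t, ref, interp = "linear", pad_value = NULL) {
  stopifnot(is_image3d(src), is_image3d(ref))
  pts <- apply_transform_point(t, grid_world_points(ref))
  vals <- sample_image(src, pts, interp, pad_value)
  image3d(array(vals, dim(ref$voxels)), ref$origin, ref$spacing, ref$direction)
}

#' Warp an integer label volume (nearest-neighbour)
#'
#' @param src_labels integer-valued [image3d] of labels.
#' @inheritParams warp_image
#' @return label [image3d] on the reference grid; background (outside the
#'   source footprint) is 0.
#' @export
warp_labels <- function(src_labels, t, ref) {
  if (max(abs(src_labels$voxels - round(src_labels$voxels))) > 0)
    stop("label volume must be integer-valued")
  warp_image(src_labels, t, ref, interp = "nearest", pad_value = 0)
}

#' Dense displacement field of a transform over a reference grid
#'
#' @inheritParams warp_image
#' @return array `(nx, ny, nz, 3)` of total displacements `T(x) - x` in mm.
#' @export
transform_to_field <- function(t, ref) {
  pts <- grid_world_points(ref)
  disp <- apply_transform_point(t, pts) - pts
  array(disp, c(dim(ref$voxels), 3))
}

# Minimum Jacobian determinant of the mapping over the interior of the
# reference grid (central differences on the dense field); < 0 means folding.
jacobian_min <- function(t, ref) {
  fld <- transform_to_field(t, ref)
  d <- dim(ref$voxels)
  if (any(d < 3)) return(NA_real_)
  # map world displacement to derivatives along grid axes (axis-aligned refs)
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  gx <- function(cmp) (fld[ii + 1, jj, kk, cmp] - fld[ii - 1, jj, kk, cmp]) /
    (2 * ref$spacing[1])
  gy <- function(cmp) (fld[ii, jj + 1, kk, cmp] - fld[ii, jj - 1, kk, cmp]) /
    (2 * ref$spacing[2])
  gz <- function(cmp) (fld[ii, jj, kk + 1, cmp] - fld[ii, jj, kk - 1, cmp]) /
    (2 * ref$spacing[3])
  a11 <- 1 + gx(1); a12 <- gy(1); a13 <- gz(1)
  a21 <- gx(2); a22 <- 1 + gy(2); a23 <- gz(2)
  a31 <- gx(3); a32 <- gy(3); a33 <- 1 + gz(3)
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  min(det)
}
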
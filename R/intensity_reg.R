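#' Registration configuration
#'
#' Collects the knobs of the intensity-driven engine. Defaults follow the
#' package's standard protocol: normalized mutual information with 64 bins,
#' gradient ascent, a three-level Gaussian image pyramid, an initial control
#' spacing of 20 mm halved at each finer level, and linear interpolation
#' during optimization.
#'
#' @param metric one of `nmi`, `mi`, `ssd`, `cc`, `je`, `cr`.
#' @param bins histogram bins for the information metrics.
#' @param optimizer `gradient` (step-halving gradient ascent) or `steepest`
#'   (golden-section line search).
#' @param max_iter iterations per pyramid level (scalar, or vector from
#'   coarsest to finest).
#' @param pyramid_levels number of resolution levels (>= 1).
#' @param control_spacing0 FFD control spacing at the coarsest level, mm.
#' @param spacing_halving halve the control spacing at each finer level
#'   (by dyadic lattice subdivision, which preserves the displacement field).
#' @param interp interpolator used when sampling the source.
#' @param mask optional logical array on the target grid.
#' @param init_transform optional initial transform (`dof_in` semantics): the
#'   optimization starts from it and it is carried into the result.
#' @param step initial optimizer step in mm; defaults to 1 mm for linear
#'   models and 0.4 x control spacing for FFD.
#' @param min_step,tol,h optimizer termination / finite-difference controls.
#' @param ridge ridge weight for landmark FFD fits.
#' @export
reg_config <- function(metric = "nmi", bins = 64, optimizer = "gradient",
                       max_iter = 20, pyramid_levels = 3,
                       control_spacing0 = 20, spacing_halving = TRUE,
                       interp = "linear", mask = NULL, init_transform = NULL,
                       step = NULL, min_step = 0.05, tol = 1e-6, h = 0.5,
                       ridge = 1e-6) {
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (control_spacing0 <= 0) stop("control_spacing0 must be positive")
  structure(list(metric = metric, bins = as.integer(bins),
                 optimizer = optimizer, max_iter = max_iter,
                 pyramid_levels = as.integer(pyramid_levels),
                 control_spacing0 = control_spacing0,
                 spacing_halving = isTRUE(spacing_halving), interp = interp,
                 mask = mask, init_transform = init_transform, step = step,
                 min_step = min_step, tol = tol, h = h, ridge = ridge),
            class = "reg_config")
}

require_axis_aligned <- function(img, what) {
  if (max(abs(img$direction - diag(3))) > 1e-9)
    stop(what, " must be axis-aligned for registration; use reorient_to()/",
         "resample_to_reference() first")
}

# Frozen histogram ranges per level: the target range and the source volume
# range (the source voxels themselves never change during optimization, so
# both ranges are stationary); the pad value is the source minimum and
# therefore inside the range.
level_ranges <- function(tgt, src) {
  list(a = range(tgt$voxels, finite = TRUE), b = range(src$voxels, finite = TRUE))
}

level_metric <- function(cfg, tgt, warped, src_range, tgt_range) {
  fn <- metric_fn(cfg$metric, cfg$bins)
  fn(tgt, warped, mask = NULL, range_a = tgt_range, range_b = src_range)
}

per_level <- function(x, level, levels) {
  x <- rep_len(x, levels)
  x[level]
}

## --- linear (rigid / affine) ------------------------------------------------

linear_params0 <- function(model, init) {
  g <- if (is.null(init)) NULL else as_composite(init)$global
  if (model == "rigid") {
    if (is.null(g)) return(numeric(6))
    if (!inherits(g, "rigid_transform"))
      stop("rigid registration cannot start from a non-rigid global transform")
    c(g$translation, rotation_to_euler(g$rotation))
  } else {
    if (is.null(g)) return(c(as.vector(diag(3)), 0, 0, 0))
    c(as.vector(linear_matrix(g)), g$translation)
  }
}

rotation_to_euler <- function(R) {
  # ZYX convention: R = Rz(c) Ry(b) Rx(a)
  b <- asin(-R[3, 1])
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c)
}

euler_to_rotation <- function(abc) {
  a <- abc[1]; b <- abc[2]; cc <- abc[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(cc), -sin(cc), 0), c(sin(cc), cos(cc), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

params_to_linear <- function(model, par) {
  if (model == "rigid")
    rigid_transform(euler_to_rotation(par[4:6]), par[1:3])
  else
    affine_transform(matrix(par[1:9], 3, 3), par[10:12])
}

#' Intensity-based rigid or affine registration
#'
#' Optimizes the 6 rigid or 12 affine parameters to maximize the configured
#' similarity metric over a Gaussian image pyramid. Parameters are scaled
#' internally so one optimizer unit moves the image periphery by about one
#' millimetre, which lets translations, rotations and scalings share a step
#' length.
#'
#' @param target fixed [image3d] (the reference frame).
#' @param source moving [image3d].
#' @param model `"rigid"` or `"affine"`.
#' @param cfg a [reg_config].
#' @return list with `transform` (a [composite_transform]), `initial_metric`,
#'   `final_metric` and per-level optimizer `states`.
#' @export
register_linear <- function(target, source, model = c("rigid", "affine"),
                            cfg = reg_config()) {
  model <- match.arg(model)
  stopifnot(is_image3d(target), is_image3d(source))
  require_axis_aligned(target, "target")
  pyr_t <- build_pyramid(target, cfg$pyramid_levels)
  pyr_s <- build_pyramid(source, cfg$pyramid_levels)
  par <- linear_params0(model, cfg$init_transform)
  ext <- max(image_bounds(target)$upper - image_bounds(target)$lower)
  # unit scales: translations in mm; rotation / matrix entries scaled so one
  # unit displaces a point at half the field of view by one mm
  scales <- if (model == "rigid") c(1, 1, 1, rep(2 / ext, 3))
            else c(rep(2 / ext, 9), 1, 1, 1)
  centre <- (image_bounds(target)$upper + image_bounds(target)$lower) / 2
  states <- vector("list", cfg$pyramid_levels)
  init_locals <- if (is.null(cfg$init_transform)) list()
                 else as_composite(cfg$init_transform)$locals
  rng_full <- level_ranges(target, source)
  w0 <- warp_image(source,
                   composite_transform(params_to_linear(model, par), init_locals),
                   target, cfg$interp)
  initial_metric <- level_metric(cfg, target, w0, rng_full$b, rng_full$a)
  for (level in seq.int(cfg$pyramid_levels, 1L)) {
    tgt <- pyr_t[[level]]; src <- pyr_s[[level]]
    rng <- level_ranges(tgt, src)
    objective <- function(z) {
      t0 <- composite_transform(
        params_to_linear(model, centre_params(model, z * scales, centre)),
        init_locals)
      w <- warp_image(src, t0, tgt, cfg$interp)
      level_metric(cfg, tgt, w, rng$b, rng$a)
    }
    z0 <- decentre_params(model, par, centre) / scales
    ocfg <- list(max_iter = per_level(cfg$max_iter, cfg$pyramid_levels - level + 1L,
                                      cfg$pyramid_levels),
                 initial_step = if (is.null(cfg$step)) 1 else cfg$step,
                 min_step = cfg$min_step, tol = cfg$tol, h = cfg$h)
    fit <- if (identical(cfg$optimizer, "steepest"))
      steepest_ascent(objective, z0, ocfg)
    else gradient_ascent(objective, z0, ocfg)
    par <- centre_params(model, fit$params * scales, centre)
    states[[level]] <- fit$state
  }
  t_final <- params_to_linear(model, par)
  res <- composite_transform(global = t_final, locals = init_locals)
  w <- warp_image(source, res, target, cfg$interp)
  rng <- level_ranges(target, source)
  list(transform = res,
       initial_metric = initial_metric,
       final_metric = level_metric(cfg, target, w, rng$b, rng$a),
       states = states)
}

# Rotations/scalings are parameterized about the image centre so that the
# optimizer's translation and linear parts are decoupled; stored transforms
# are always about the world origin.
centre_params <- function(model, par, centre) {
  if (model == "rigid") {
    R <- euler_to_rotation(par[4:6])
    c(centre + par[1:3] - as.numeric(R %*% centre), par[4:6])
  } else {
    A <- matrix(par[1:9], 3, 3)
    c(par[1:9], centre + par[10:12] - as.numeric(A %*% centre))
  }
}

decentre_params <- function(model, par, centre) {
  if (model == "rigid") {
    R <- euler_to_rotation(par[4:6])
    c(par[1:3] - centre + as.numeric(R %*% centre), par[4:6])
  } else {
    A <- matrix(par[1:9], 3, 3)
    c(par[1:9], par[10:12] - centre + as.numeric(A %*% centre))
  }
}

## --- FFD --------------------------------------------------------------------

#' Multi-resolution B-spline FFD registration
#'
#' Free-form deformation registration over a Gaussian image pyramid. The
#' control lattice covers the whole target domain plus a one-spacing margin;
#' its spacing starts at `control_spacing0` on the coarsest level and is
#' halved at each finer level by dyadic subdivision, which carries the
#' displacement field across levels. All control points are free. The
#' optimizer maximizes the configured metric (NMI by default) of the target
#' against the warped source; for NMI the gradient uses the local-support
#' fast path (only the histogram contributions of voxels within a control
#' point's support are updated).
#'
#' @inheritParams register_linear
#' @return list with `transform` (init transform plus the optimized lattice),
#'   `initial_metric`, `final_metric`, per-level `states` and the final
#'   `lattice`.
#' @export
register_ffd <- function(target, source, cfg = reg_config()) {
  stopifnot(is_image3d(target), is_image3d(source))
  require_axis_aligned(target, "target")
  require_axis_aligned(source, "source")
  init <- as_composite(cfg$init_transform)
  levels <- cfg$pyramid_levels
  pyr_t <- build_pyramid(target, levels)
  pyr_s <- build_pyramid(source, levels)
  spacing0 <- cfg$control_spacing0
  lat <- ffd_lattice_covering(target, spacing0)
  states <- vector("list", levels)
  rng_full <- level_ranges(target, source)
  w0 <- warp_image(source, init, target, cfg$interp)
  initial_metric <- level_metric(cfg, target, w0, rng_full$b, rng_full$a)
  for (step_level in seq_len(levels)) {
    level <- levels - step_level + 1L  # pyramid index, coarsest first
    tgt <- pyr_t[[level]]; src <- pyr_s[[level]]
    if (any(lat$shape < 4L))
      stop("control lattice has fewer than 4 points per axis; ",
           "increase control_spacing0 or image size")
    opt <- optimize_ffd_level(tgt, src, init, lat, cfg,
                              per_level(cfg$max_iter, step_level, levels))
    lat <- opt$lattice
    states[[step_level]] <- opt$state
    if (step_level < levels && cfg$spacing_halving) lat <- subdivide_lattice(lat)
  }
  res <- composite_transform(global = init$global,
                             locals = c(init$locals, list(lat)))
  w <- warp_image(source, res, target, cfg$interp)
  rng <- level_ranges(target, source)
  list(transform = res, lattice = lat,
       initial_metric = initial_metric,
       final_metric = level_metric(cfg, target, w, rng$b, rng$a),
       states = states)
}

# One pyramid level of FFD optimization. The fixed part of the mapping
# (global + previously fitted lattices) is evaluated once; the active
# lattice's displacement is added on top (the additive local model).
optimize_ffd_level <- function(tgt, src, init, lat, cfg, max_iter) {
  pts <- grid_world_points(tgt)
  fixed_pts <- apply_transform_point(init, pts)
  rng <- level_ranges(tgt, src)
  bins <- cfg$bins
  wa <- bin_width(rng$a, bins); wb <- bin_width(rng$b, bins)
  tgt_bin <- c_bin_values(as.numeric(tgt$voxels), rng$a[1], wa, bins)
  pad <- min(src$voxels)
  sdim <- dim(src$voxels); rdim <- dim(tgt$voxels)
  step_idx <- t(src$direction) / src$spacing  # d(src index)/d(world mm)
  nc <- prod(lat$shape)
  coef0 <- as.numeric(lat$coefficients)
  free3 <- rep(as.logical(lat$free_mask), 3L)

  src_idx_of <- function(coefvec) {
    l2 <- lat; l2$coefficients <- array(coefvec, c(lat$shape, 3))
    world_to_voxel(src, fixed_pts + ffd_displacement(l2, pts))
  }
  objective <- function(coefvec) {
    vals <- c_interp(as.numeric(src$voxels), sdim, src_idx_of(coefvec),
                     interp_code(cfg$interp), pad)
    bb <- c_bin_values(vals, rng$b[1], wb, bins)
    h <- c_hist_from_bins(tgt_bin, bb, bins)
    e <- c_hist_entropies(h)
    score_from_entropies(cfg$metric, e, tgt, vals)
  }
  use_fast_grad <- identical(cfg$metric, "nmi") && identical(cfg$interp, "linear")
  gradient_fn <- NULL
  if (use_fast_grad) {
    g0 <- (tgt$origin - lat$grid_origin) / lat$spacing
    gd <- tgt$spacing / lat$spacing
    gradient_fn <- function(coefvec) {
      idx <- src_idx_of(coefvec)
      vals <- c_interp(as.numeric(src$voxels), sdim, idx, 1L, pad)
      base_bin <- c_bin_values(vals, rng$b[1], wb, bins)
      c_nmi_grad_ffd(as.numeric(src$voxels), sdim, rdim, idx, base_bin,
                     tgt_bin, lat$shape, as.logical(lat$free_mask),
                     g0, gd, step_idx, bins, rng$b[1], wb, cfg$h, pad)
    }
  }
  step0 <- if (is.null(cfg$step)) 0.4 * min(lat$spacing) else cfg$step
  ocfg <- list(max_iter = max_iter, initial_step = step0,
               min_step = cfg$min_step, tol = cfg$tol, h = cfg$h,
               free = free3)
  fit <- if (identical(cfg$optimizer, "steepest"))
    steepest_ascent(objective, coef0, ocfg, gradient_fn = gradient_fn)
  else gradient_ascent(objective, coef0, ocfg, gradient_fn = gradient_fn)
  lat$coefficients <- array(fit$params, c(lat$shape, 3))
  list(lattice = lat, state = fit$state,
       initial_metric = fit$state$history[1, "objective"])
}

# Metric evaluation from a prebuilt joint histogram (information metrics) or
# from raw values (ssd / cc need no histogram).
score_from_entropies <- function(metric, e, tgt, vals) {
  switch(metric,
    nmi = (e[1] + e[2]) / e[3],
    mi = e[1] + e[2] - e[3],
    je = -e[3],
    ssd = -mean((as.numeric(tgt$voxels) - vals)^2),
    cc = stats::cor(as.numeric(tgt$voxels), vals),
    cr = stop("correlation ratio is not supported as an FFD objective"),
    stop("unknown metric '", metric, "'"))
}

#' Multi-phase registration: landmark FFD then intensity FFD
#'
#' The two-stage strategy for locally large deformations: phase 1 fits a
#' landmark-driven FFD (LFFD) whose free control points are restricted to a
#' region of interest (e.g. the thigh region), using corresponding landmark
#' sets in target and source; phase 2 runs intensity-based FFD registration
#' starting from that correction, with the phase-1 lattice frozen and a fresh
#' all-free lattice optimized on top (the additive two-term local model).
#' The LFFD phase fits a coarse-to-fine sequence of ROI-masked lattices
#' (spacing halving from `cfg_lffd$control_spacing0`), each on the residual
#' landmark error of the previous.
#'
#' @inheritParams register_linear
#' @param thigh_roi [roi_box] bounding the locally large deformation.
#' @param P,Q corresponding [landmark_set]s in target and source (inside the
#'   ROI region).
#' @param cfg_lffd [reg_config] for the landmark phase (`control_spacing0`,
#'   `pyramid_levels` = number of halvings, `ridge`, `init_transform`).
#' @param cfg_ffd [reg_config] for the intensity phase.
#' @return as [register_ffd()], plus `lffd_lattices` and landmark errors
#'   `tre_before` / `tre_after_lffd` (mm).
#' @export
register_multiphase <- function(target, source, thigh_roi, P, Q,
                                cfg_lffd = reg_config(control_spacing0 = 40),
                                cfg_ffd = reg_config()) {
  stopifnot(is_image3d(target), is_image3d(source))
  init <- as_composite(cfg_lffd$init_transform)
  pq <- check_pairs(P, Q, 1L)
  tre0 <- landmark_tre(P, Q, init)
  # account for the initial transform: the lattices must explain the residual
  base <- apply_transform_point(init, pq$p)
  lffd_lats <- list()
  spacing <- cfg_lffd$control_spacing0
  for (lev in seq_len(cfg_lffd$pyramid_levels)) {
    lat <- ffd_lattice_covering(target, spacing, roi = thigh_roi)
    if (sum(lat$free_mask) > 0L) {
      q_eff <- landmark_set(Q$names, pq$q - base + pq$p)
      lat <- fit_lffd(P, q_eff, lat, ridge = cfg_lffd$ridge)
      base <- base + ffd_displacement(lat, pq$p)
      lat$free_mask[] <- FALSE  # frozen for phase 2
      lffd_lats[[length(lffd_lats) + 1L]] <- lat
    }
    spacing <- spacing / 2
  }
  t_phase1 <- composite_transform(global = init$global,
                                  locals = c(init$locals, lffd_lats))
  tre1 <- landmark_tre(P, Q, t_phase1)
  cfg2 <- cfg_ffd
  cfg2$init_transform <- t_phase1
  out <- register_ffd(target, source, cfg2)
  out$lffd_lattices <- lffd_lats
  out$tre_before <- tre0$mean
  out$tre_after_lffd <- tre1$mean
  out
}

#' Registration quality report
#'
#' Deterministic metric summary of a registered pair: Pearson correlation,
#' NMI, per-label Dice (when label volumes are given) and the minimum
#' Jacobian determinant of the mapping (when the transform is given;
#' negative values indicate folding).
#'
#' @param target fixed [image3d].
#' @param warped_source source already warped onto the target grid.
#' @param labels_target,warped_labels optional integer label volumes on the
#'   target grid.
#' @param transform optional transform for the Jacobian summary.
#' @param bins histogram bins for NMI.
#' @return list with `cc`, `nmi`, `dice` (named by label) and `jacobian_min`.
#' @export
evaluate_registration <- function(target, warped_source, labels_target = NULL,
                                  warped_labels = NULL, transform = NULL,
                                  bins = 64) {
  stopifnot(is_image3d(target), is_image3d(warped_source))
  if (!same_grid(target, warped_source))
    stop("evaluation requires target and warped source on one grid")
  rep <- list(cc = pearson_cc(target, warped_source),
              nmi = nmi(target, warped_source, bins = bins))
  if (!is.null(labels_target) && !is.null(warped_labels)) {
    la <- labels_target$voxels; lb <- warped_labels$voxels
    labs <- sort(setdiff(unique(as.vector(la)), 0))
    dice <- vapply(labs, function(l) {
      a <- la == l; b <- lb == l
      2 * sum(a & b) / (sum(a) + sum(b))
    }, 0)
    names(dice) <- labs
    rep$dice <- dice
  }
  rep$jacobian_min <- if (is.null(transform)) NA_real_
                      else jacobian_min(transform, target)
  rep
}
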
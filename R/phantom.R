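# Synthetic pelvic phantom generator. The anatomy is an analytic intensity
# function (smooth body ellipsoid, a high-intensity pelvic ring, bladder /
# rectum / tumor blobs and two lateral thigh cylinders) evaluated directly in
# world coordinates, so a warped copy of the anatomy can be produced without
# interpolation error: the target image is f(T(x)) for the ground-truth
# transform T and the source image is f(y). T therefore maps the target
# frame into the source frame, exactly the pull-back convention used by the
# registration engine, and registering target vs source should recover T.

phantom_geometry <- function(size, spacing) {
  size <- as.integer(rep_len(size, 3))
  spacing <- rep_len(as.numeric(spacing), 3)
  ext <- (size - 1) * spacing
  list(size = size, spacing = spacing, extent = ext, centre = ext / 2)
}

# Analytic anatomy: returns intensity for an N x 3 matrix of world points.
phantom_intensity <- function(p, geom) {
  ctr <- geom$centre; ext <- geom$extent
  x <- p[, 1] - ctr[1]; y <- p[, 2] - ctr[2]; z <- p[, 3] - ctr[3]
  soft <- function(d, w) 1 / (1 + exp(d / w))
  # soft body ellipsoid
  rb <- sqrt((x / (0.46 * ext[1]))^2 + (y / (0.40 * ext[2]))^2 +
               (z / (0.52 * ext[3]))^2)
  val <- 200 * soft((rb - 1) * 0.2 * min(ext), 2.5)
  # pelvic ring (bone-like shell)
  rp <- sqrt((x / (0.26 * ext[1]))^2 + (y / (0.20 * ext[2]))^2 +
               ((z - 0.12 * ext[3]) / (0.22 * ext[3]))^2)
  val <- val + 800 * exp(-((rp - 1) / 0.13)^2)
  # bladder (anterior, -y in LPS), rectum (posterior), central tumor
  val <- val + 260 * blob(x, y + 0.13 * ext[2], z - 0.10 * ext[3], 0.070 * min(ext))
  val <- val + 220 * blob(x, y - 0.15 * ext[2], z - 0.10 * ext[3], 0.055 * min(ext))
  val <- val + 320 * blob(x, y + 0.02 * ext[2], z - 0.05 * ext[3], 0.050 * min(ext))
  # thighs: lateral cylinders in the inferior half
  zw <- soft((z + 0.10 * ext[3]) * 6 / ext[3], 0.5)  # weight for low z
  for (s in c(-1, 1)) {
    rt <- sqrt(((x - s * 0.30 * ext[1]) / (0.105 * ext[1]))^2 +
                 ((y - 0.03 * ext[2]) / (0.16 * ext[2]))^2)
    val <- val + 380 * exp(-rt^2) * zw
  }
  val
}

blob <- function(x, y, z, sigma) exp(-(x^2 + y^2 + z^2) / (2 * sigma^2))

# Integer labels: 1 pelvis, 2 bladder, 3 rectum, 4 left thigh, 5 right thigh.
phantom_labels <- function(p, geom) {
  ctr <- geom$centre; ext <- geom$extent
  x <- p[, 1] - ctr[1]; y <- p[, 2] - ctr[2]; z <- p[, 3] - ctr[3]
  lab <- numeric(nrow(p))
  for (s in c(-1, 1)) {
    rt <- sqrt(((x - s * 0.30 * ext[1]) / (0.105 * ext[1]))^2 +
                 ((y - 0.03 * ext[2]) / (0.16 * ext[2]))^2)
    sel <- rt < 1 & z < -0.02 * ext[3]
    lab[sel] <- ifelse(s < 0, 4, 5)
  }
  rp <- sqrt((x / (0.26 * ext[1]))^2 + (y / (0.20 * ext[2]))^2 +
               ((z - 0.12 * ext[3]) / (0.22 * ext[3]))^2)
  lab[abs(rp - 1) < 0.13] <- 1
  rb <- sqrt(x^2 + (y + 0.13 * ext[2])^2 + (z - 0.10 * ext[3])^2)
  lab[rb < 1.1 * 0.070 * min(ext)] <- 2
  rr <- sqrt(x^2 + (y - 0.15 * ext[2])^2 + (z - 0.10 * ext[3])^2)
  lab[rr < 1.1 * 0.055 * min(ext)] <- 3
  lab
}

phantom_body <- function(p, geom) {
  ctr <- geom$centre; ext <- geom$extent
  x <- p[, 1] - ctr[1]; y <- p[, 2] - ctr[2]; z <- p[, 3] - ctr[3]
  rb <- sqrt((x / (0.46 * ext[1]))^2 + (y / (0.40 * ext[2]))^2 +
               (z / (0.52 * ext[3]))^2)
  rb < 1
}

# Scale lattice coefficients so the maximum displacement magnitude over the
# sampled grid equals the requested amplitude.
scale_lattice_amplitude <- function(lat, pts, amplitude) {
  d <- ffd_displacement(lat, pts)
  m <- max(sqrt(rowSums(d^2)))
  if (m <= 0) return(lat)
  lat$coefficients <- lat$coefficients * (amplitude / m)
  lat
}

#' Generate a synthetic pelvic phantom with known ground truth
#'
#' Builds a target (EBRT-like) volume and a source (HDR-BT-like) volume
#' related by a known transform: sampled global motion (rigid or affine), a
#' smooth random background FFD of amplitude `local_amplitude`, and a large
#' FFD confined to a thigh ROI of amplitude `roi_amplitude` — the locally
#' large deformation that defeats purely intensity-driven FFD. The source
#' additionally carries `n_impulses` applicator-like bright voxels inside a
#' central tube. Landmarks on the thigh cylinders are returned in both
#' frames, with the source positions mapped exactly through the truth
#' transform. Everything is reproducible from `seed`.
#'
#' @param seed integer RNG seed.
#' @param size voxels per axis (scalar or 3-vector, >= 32).
#' @param spacing voxel spacing in mm.
#' @param global `"affine"`, `"rigid"` or `"none"` global motion.
#' @param local_amplitude maximum background deformation, mm.
#' @param roi_amplitude maximum deformation inside the thigh ROI, mm.
#' @param n_impulses number of bright applicator voxels added to the source.
#' @return an object of class `phantom_truth` with fields `target`, `source`,
#'   `clean_source`, `truth_transform`, `labels_target`, `labels_source`,
#'   `landmarks_target`, `landmarks_source`, `dose_source`, `roi`,
#'   `body_target` (logical array) and `seed`.
#' @export
make_phantom <- function(seed = 1, size = 48, spacing = 3,
                         global = c("affine", "rigid", "none"),
                         local_amplitude = 4, roi_amplitude = 12,
                         n_impulses = 120) {
  global <- match.arg(global)
  geom <- phantom_geometry(size, spacing)
  if (any(geom$size < 32L)) stop("phantom size must be >= 32 voxels per axis")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  ext <- geom$extent; ctr <- geom$centre
  grid <- image3d(array(0, geom$size), origin = c(0, 0, 0),
                  spacing = geom$spacing)
  pts <- grid_world_points(grid)

  # thigh ROI: the inferior band containing both thigh cylinders
  roi <- roi_box(ctr + c(-0.44 * ext[1], -0.22 * ext[2], -0.52 * ext[3]),
                 ctr + c(0.44 * ext[1], 0.26 * ext[2], -0.06 * ext[3]))

  # --- ground-truth transform -----------------------------------------------
  g_tr <- NULL
  if (global != "none") {
    ang <- stats::rnorm(3, 0, 1.5 * pi / 180)
    tr <- stats::rnorm(3, 0, 3)
    R <- euler_to_rotation(ang)
    if (global == "rigid") {
      g_tr <- rigid_transform(R, ctr + tr - as.numeric(R %*% ctr))
    } else {
      S <- diag(1 + stats::rnorm(3, 0, 0.02))
      S[1, 2] <- stats::rnorm(1, 0, 0.015)
      A <- R %*% S
      g_tr <- affine_transform(A, ctr + tr - as.numeric(A %*% ctr))
    }
  }
  locals <- list()
  if (local_amplitude > 0) {
    lat_bg <- ffd_lattice_covering(grid, min(ext) / 4)
    lat_bg$coefficients[] <- stats::rnorm(length(lat_bg$coefficients))
    lat_bg <- scale_lattice_amplitude(lat_bg, pts, local_amplitude)
    locals <- c(locals, list(lat_bg))
  }
  if (roi_amplitude > 0) {
    # coherent per-leg repositioning: each thigh shifts along its own random
    # direction, weighted by a smooth thigh-membership profile, so the large
    # deformation rides on the thigh cylinders themselves
    lat_roi <- ffd_lattice_covering(grid, min(ext) / 6, roi = roi)
    nfree <- sum(lat_roi$free_mask)
    if (nfree == 0L) stop("phantom ROI lies outside the image domain")
    nodes <- lattice_node_world(lat_roi$grid_origin, lat_roi$spacing,
                                lat_roi$shape)
    cf <- lat_roi$coefficients
    for (s in c(-1, 1)) {
      u <- c(stats::rnorm(1, s * 1, 0.3), stats::rnorm(1, 0, 0.4),
             stats::rnorm(1, 0, 0.3))
      u <- u / sqrt(sum(u^2)) * stats::runif(1, 0.7, 1)
      nx <- (nodes[, 1] - ctr[1] - s * 0.30 * ext[1]) / (0.14 * ext[1])
      ny <- (nodes[, 2] - ctr[2] - 0.03 * ext[2]) / (0.20 * ext[2])
      nz <- (nodes[, 3] - ctr[3]) / ext[3]
      w <- exp(-(nx^2 + ny^2)) / (1 + exp((nz + 0.10) * 6 / 0.5))
      for (cmp in 1:3)
        cf[, , , cmp][lat_roi$free_mask] <- cf[, , , cmp][lat_roi$free_mask] +
          (u[cmp] * w)[lat_roi$free_mask]
    }
    lat_roi$coefficients <- cf
    lat_roi <- scale_lattice_amplitude(lat_roi, pts, roi_amplitude)
    locals <- c(locals, list(lat_roi))
  }
  truth <- composite_transform(global = g_tr, locals = locals)

  # --- images (analytic, no interpolation error) ----------------------------
  pts_warped <- apply_transform_point(truth, pts)
  target <- image3d(array(phantom_intensity(pts_warped, geom), geom$size),
                    grid$origin, grid$spacing)
  clean_source <- image3d(array(phantom_intensity(pts, geom), geom$size),
                          grid$origin, grid$spacing)
  labels_target <- image3d(array(phantom_labels(pts_warped, geom), geom$size),
                           grid$origin, grid$spacing)
  labels_source <- image3d(array(phantom_labels(pts, geom), geom$size),
                           grid$origin, grid$spacing)
  body_target <- array(phantom_body(pts_warped, geom), geom$size)

  # applicator-like impulse noise: bright voxels inside a central tube of the
  # source (positive-only, at least 3x the tissue maximum)
  source <- clean_source
  if (n_impulses > 0) {
    tube <- which(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <
                    0.10 * min(ext[1:2]))
    tube <- tube[pts[tube, 3] > ctr[3] - 0.45 * ext[3] &
                   pts[tube, 3] < ctr[3] + 0.35 * ext[3]]
    pick <- sample(tube, min(n_impulses, length(tube)))
    vmax <- max(clean_source$voxels)
    source$voxels[pick] <- 3 * vmax + stats::runif(length(pick), 0, vmax)
  }

  # thigh landmarks (target frame, inside the ROI), mapped exactly by truth:
  # two rings of four points around each thigh cylinder plus the axis ends,
  # the sort of spread a user picks when marking a structure in 3D
  zl <- ctr[3] + ext[3] * c(-0.38, -0.14)
  rad <- 0.09 * ext[1]
  lp <- NULL
  for (s in c(-1, 1)) {
    ax <- ctr[1] + s * 0.30 * ext[1]; ay <- ctr[2] + 0.03 * ext[2]
    for (z in zl)
      for (th in c(0, pi / 2, pi, 3 * pi / 2))
        lp <- rbind(lp, c(ax + rad * cos(th), ay + rad * sin(th), z))
    lp <- rbind(lp, c(ax, ay, ctr[3] - 0.26 * ext[3]))
  }
  keep <- roi_contains(roi, lp)
  lp <- lp[keep, , drop = FALSE]
  side <- rep(c("thigh_L_", "thigh_R_"), each = 9)[keep]
  lnames <- paste0(side, seq_len(nrow(lp)))
  landmarks_target <- landmark_set(lnames, lp)
  landmarks_source <- landmark_set(lnames, apply_transform_point(truth, lp))

  dose_source <- make_dose_internal(geom, grid, "gaussian_blob")

  structure(list(target = target, source = source, clean_source = clean_source,
                 truth_transform = truth, labels_target = labels_target,
                 labels_source = labels_source,
                 landmarks_target = landmarks_target,
                 landmarks_source = landmarks_source,
                 dose_source = dose_source, roi = roi,
                 body_target = body_target, geom = geom,
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

make_dose_internal <- function(geom, grid, pattern, peak_gy = 7, uniform_gy = 2) {
  pts <- grid_world_points(grid)
  if (pattern == "uniform") {
    vals <- rep(uniform_gy, nrow(pts))
  } else {
    tc <- geom$centre + c(0, -0.02 * geom$extent[2], 0.05 * geom$extent[3])
    sig <- 0.12 * min(geom$extent)
    vals <- peak_gy * exp(-rowSums(sweep(pts, 2, tc)^2) / (2 * sig^2))
  }
  dose_grid(array(vals, geom$size), grid$origin, grid$spacing,
            fraction_label = pattern)
}

#' Synthetic dose grid for a phantom
#'
#' Either a uniform field or a Gaussian blob centred on the phantom's tumor,
#' on the source geometry (the frame a brachytherapy dose lives in).
#'
#' @param truth a [make_phantom()] result.
#' @param pattern `"uniform"` (2 Gy everywhere) or `"gaussian_blob"`
#'   (7 Gy peak at the tumor centre).
#' @return a [dose_grid].
#' @export
make_dose <- function(truth, pattern = c("gaussian_blob", "uniform")) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(truth, "phantom_truth"))
  grid <- truth$clean_source
  make_dose_internal(truth$geom, grid, pattern)
}
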
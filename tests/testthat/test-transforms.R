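test_that("uniform cubic B-spline basis matches its closed form", {
  expect_equal(sapply(0:3, bspline_basis, t = 0),
               c(1 / 6, 2 / 3, 1 / 6, 0), tolerance = 1e-15)
  # direct evaluation of the published polynomial pieces at t = 0.5
  t <- 0.5
  expect_equal(bspline_basis(0, t), (1 - t)^3 / 6, tolerance = 1e-15)
  expect_equal(bspline_basis(1, t), (3 * t^3 - 6 * t^2 + 4) / 6, tolerance = 1e-15)
  expect_equal(bspline_basis(2, t), (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
               tolerance = 1e-15)
  expect_equal(bspline_basis(3, t), t^3 / 6, tolerance = 1e-15)
  set.seed(31)
  tt <- runif(1000)
  s <- bspline_basis(0, tt) + bspline_basis(1, tt) + bspline_basis(2, tt) +
    bspline_basis(3, tt)
  expect_lt(max(abs(s - 1)), 1e-12)
  expect_error(bspline_basis(4, 0.5), "0,1,2,3")
  expect_error(bspline_basis(1, 1.0), "\\[0, 1\\)")
})

make_random_lattice <- function(shape = c(6, 6, 6), spacing = c(10, 10, 10),
                                origin = c(-10, -10, -10)) {
  ffd_lattice(origin, spacing, shape,
              coefficients = array(rnorm(prod(shape) * 3), c(shape, 3)))
}

test_that("FFD displacement matches the naive triple-loop oracle", {
  set.seed(32)
  lat <- make_random_lattice()
  zero <- ffd_lattice(c(-10, -10, -10), c(10, 10, 10), c(6, 6, 6))
  p <- matrix(runif(300, 5, 25), 100, 3)
  expect_true(all(ffd_displacement(zero, p) == 0))
  d <- ffd_displacement(lat, p)
  for (i in seq_len(nrow(p)))
    expect_equal(d[i, ], oracle_ffd_disp(lat, p[i, ]), tolerance = 1e-10)
})

test_that("a single displaced control point contributes B1(0)^3 at its node", {
  lat <- ffd_lattice(c(0, 0, 0), c(10, 10, 10), c(7, 7, 7))
  lat$coefficients[4, 4, 4, ] <- c(9, -6, 3)
  # world position of node (3,3,3) (0-based) = 30,30,30; u=v=w=0 there
  d <- ffd_displacement(lat, c(30, 30, 30))
  expect_equal(as.numeric(d), (2 / 3)^3 * c(9, -6, 3), tolerance = 1e-12)
})

test_that("constant coefficients displace every interior point by the constant", {
  lat <- ffd_lattice(c(-20, -20, -20), c(10, 15, 20), c(7, 7, 7))
  lat$coefficients[, , , 1] <- 4.5
  lat$coefficients[, , , 2] <- -2.25
  lat$coefficients[, , , 3] <- 0.125
  set.seed(33)
  p <- cbind(runif(50, 0, 20), runif(50, 0, 30), runif(50, 0, 40))
  d <- ffd_displacement(lat, p)
  expect_lt(max(abs(sweep(d, 2, c(4.5, -2.25, 0.125)))), 1e-10)
})

test_that("smooth-mode displacement vanishes beyond two spacings from free nodes", {
  lat <- ffd_lattice(c(0, 0, 0), c(10, 10, 10), c(11, 11, 11),
                     roi = roi_box(c(30, 30, 30), c(70, 70, 70)))
  # restrict free nodes strictly to the ROI interior
  nodes <- rtfuse:::lattice_node_world(lat$grid_origin, lat$spacing, lat$shape)
  lat$free_mask <- array(rtfuse:::roi_contains(lat$roi, nodes), lat$shape)
  set.seed(34)
  lat$coefficients[, , , 1][lat$free_mask] <- rnorm(sum(lat$free_mask))
  far <- rbind(c(5, 50, 50), c(50, 95, 50), c(95, 95, 95), c(50, 50, 5))
  expect_lt(max(abs(ffd_displacement(lat, far))), 1e-12)
  near <- matrix(c(50, 50, 50), 1)
  expect_gt(max(abs(ffd_displacement(lat, near))), 0)
})

test_that("strict piecewise mode forces the identity outside the ROI box", {
  roi <- roi_box(c(20, 20, 20), c(40, 40, 40))
  set.seed(35)
  lat <- ffd_lattice(c(-10, -10, -10), c(10, 10, 10), c(8, 8, 8),
                     coefficients = array(rnorm(8^3 * 3), c(8, 8, 8, 3)),
                     roi = roi, strict_piecewise = TRUE)
  expect_true(all(ffd_displacement(lat, c(45, 30, 30)) == 0))
  expect_false(all(ffd_displacement(lat, c(30, 30, 30)) == 0))
})

test_that("composite transforms apply additively", {
  p <- matrix(rnorm(30, 0, 20), 10, 3)
  expect_equal(apply_transform_point(composite_transform(), p), p)
  tr <- rigid_transform(diag(3), c(3, -1, 2))
  expect_equal(apply_transform_point(tr, p),
               p + matrix(c(3, -1, 2), 10, 3, byrow = TRUE))
  set.seed(36)
  R <- random_rotation()
  rig <- rigid_transform(R, c(1, 2, 3))
  lat <- make_random_lattice(origin = c(-40, -40, -40), spacing = c(15, 15, 15),
                             shape = c(8, 8, 8))
  comp <- composite_transform(rig, list(lat))
  manual <- p %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE) +
    ffd_displacement(lat, p)
  expect_equal(apply_transform_point(comp, p), manual, tolerance = 1e-12)
})

test_that("warping with the identity equals resampling; integer shifts shift", {
  set.seed(37)
  src <- test_image(c(10, 10, 10), spacing = c(2, 2, 2))
  idw <- warp_image(src, composite_transform(), src)
  expect_equal(idw$voxels, resample_to_reference(src, src)$voxels, tolerance = 0)

  sh <- warp_image(src, rigid_transform(diag(3), c(2, 0, 0)), src)
  expect_equal(sh$voxels[1:9, , ], src$voxels[2:10, , ], tolerance = 1e-12)
})

test_that("FFD warp of a ramp matches a per-point transform+interpolate oracle", {
  set.seed(38)
  src <- image3d(array(rnorm(16^3), c(16, 16, 16)), spacing = c(2, 2, 2))
  lat <- make_random_lattice(origin = c(-12, -12, -12), spacing = c(8, 8, 8),
                             shape = c(8, 8, 8))
  lat$coefficients <- lat$coefficients * 1.5
  t <- composite_transform(locals = list(lat))
  w <- warp_image(src, t, src, interp = "linear", pad_value = 0)
  vox_idx <- cbind(sample(0:15, 50, TRUE), sample(0:15, 50, TRUE),
                   sample(0:15, 50, TRUE))
  for (i in 1:50) {
    world <- voxel_to_world(src, vox_idx[i, ])
    moved <- world + oracle_ffd_disp(lat, as.numeric(world))
    expected <- rtfuse:::sample_image(src, moved, "linear", 0)
    expect_equal(w$voxels[vox_idx[i, 1] + 1, vox_idx[i, 2] + 1, vox_idx[i, 3] + 1],
                 as.numeric(expected), tolerance = 1e-8)
  }
})

test_that("label warping is nearest-neighbour and closed over the label set", {
  labs <- array(sample(c(0, 2, 5), 8^3, TRUE), c(8, 8, 8))
  src <- image3d(labs, spacing = c(1, 1, 1))
  idw <- warp_labels(src, composite_transform(), src)
  expect_identical(idw$voxels, src$voxels)
  half <- warp_labels(src, rigid_transform(diag(3), c(0.5, 0.25, 0)), src)
  expect_true(all(half$voxels %in% c(0, 2, 5)))
  bad <- image3d(labs + 0.5)
  expect_error(warp_labels(bad, composite_transform(), src), "integer")
})

test_that("transform JSON round-trips bit-exactly and agrees pointwise", {
  tmp <- withr::local_tempfile(fileext = ".tfm.json")
  write_transform(composite_transform(), tmp)
  ident <- read_transform(tmp)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform_point(ident, p), p)

  set.seed(39)
  R <- random_rotation()
  lat <- make_random_lattice(shape = c(5, 6, 7))
  lat2 <- ffd_lattice(c(0, 0, 0), c(12, 12, 12), c(4, 4, 5),
                      roi = roi_box(c(5, 5, 5), c(30, 30, 30)),
                      strict_piecewise = TRUE)
  comp <- composite_transform(rigid_transform(R, c(0.1, -0.2, 0.3)),
                              list(lat, lat2))
  write_transform(comp, tmp)
  back <- read_transform(tmp)
  expect_identical(back$locals[[1]]$coefficients, lat$coefficients)
  expect_identical(back$locals[[2]]$strict_piecewise, TRUE)
  q <- matrix(rnorm(300, 0, 25), 100, 3)
  expect_equal(apply_transform_point(back, q), apply_transform_point(comp, q),
               tolerance = 1e-12)

  writeLines('{"format": "rtfuse-transform-v1", "global_type": "identity"}', tmp)
  expect_error(read_transform(tmp), "missing field 'global'")
})

test_that("dense displacement-field export equals analytic evaluation", {
  set.seed(40)
  ref <- test_image(c(8, 8, 8), spacing = c(3, 3, 3))
  lat <- make_random_lattice(origin = c(-12, -12, -12), spacing = c(10, 10, 10),
                             shape = c(6, 6, 6))
  fld <- transform_to_field(composite_transform(locals = list(lat)), ref)
  v <- c(3, 5, 2)
  expect_equal(fld[v[1] + 1, v[2] + 1, v[3] + 1, ],
               as.numeric(ffd_displacement(lat, voxel_to_world(ref, v))),
               tolerance = 1e-12)
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_displacement_field(composite_transform(locals = list(lat)), ref, tmp)
  nim <- RNifti::readNifti(tmp)
  expect_equal(dim(nim), c(8, 8, 8, 3))
  expect_equal(as.array(nim)[4, 6, 3, ],
               fld[4, 6, 3, ], tolerance = 1e-6)
})

test_that("lattice subdivision halves spacing and preserves the field", {
  set.seed(41)
  lat <- make_random_lattice(shape = c(7, 7, 7), spacing = c(12, 12, 12),
                             origin = c(-12, -12, -12))
  sub <- rtfuse:::subdivide_lattice(lat)
  expect_equal(sub$spacing, lat$spacing / 2)
  expect_equal(sub$shape, 2L * lat$shape - 1L)
  # interior points (full support in both lattices) keep their displacement
  p <- cbind(runif(200, 12, 36), runif(200, 12, 36), runif(200, 12, 36))
  expect_lt(max(abs(ffd_displacement(sub, p) - ffd_displacement(lat, p))), 1e-10)
})
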
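# Registration engine unit tests on small, fast problems; the full phantom
# recovery studies live in the acceptance suite.

blob_image <- function(centres, amps, sigmas, d = c(24, 24, 24), spacing = 2) {
  pts <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1,
                               seq_len(d[3]) - 1)) * spacing
  v <- numeric(nrow(pts))
  for (i in seq_len(nrow(centres)))
    v <- v + amps[i] * exp(-rowSums(sweep(pts, 2, centres[i, ])^2) /
                             (2 * sigmas[i]^2))
  image3d(array(v, d), spacing = rep(spacing, 3))
}

# source = target pushed through "scale about the centre, then shift":
# blob centres map and blob widths scale, so the source really is the
# affinely warped target (in the pull-back sense used by the engine)
two_blob <- function(shift = c(0, 0, 0), scale = 1) {
  # blobs kept compact and central so the warped field of view always
  # covers them (border padding must not dominate the objective)
  ctr <- rbind(c(18, 20, 26), c(29, 26, 20))
  sig <- c(6, 5)
  ctr2 <- sweep(sweep(ctr, 2, c(23, 23, 23)) * scale, 2, c(23, 23, 23) + shift, "+")
  list(target = blob_image(ctr, c(100, 60), sig),
       source = blob_image(ctr2, c(100, 60), sig * scale))
}

test_that("self-registration returns (nearly) the identity", {
  pair <- two_blob()
  fit <- register_linear(pair$target, pair$target, "rigid",
                         reg_config(metric = "ssd", pyramid_levels = 2,
                                    max_iter = 10))
  expect_lt(max(abs(fit$transform$global$translation)), 0.1)
  expect_gte(fit$final_metric, fit$initial_metric)
})

test_that("rigid registration recovers a pure translation", {
  pair <- two_blob(shift = c(6, -4, 2))
  fit <- register_linear(pair$target, pair$source, "rigid",
                         reg_config(metric = "ssd", pyramid_levels = 3,
                                    max_iter = 25))
  p0 <- c(23, 23, 23)
  got <- as.numeric(apply_transform_point(fit$transform, p0) - p0)
  expect_lt(max(abs(got - c(6, -4, 2))), 0.5)
  expect_gte(fit$final_metric, fit$initial_metric)
})

test_that("affine registration recovers a 5% scaling", {
  pair <- two_blob(scale = 1.05)
  fit <- register_linear(pair$target, pair$source, "affine",
                         reg_config(metric = "ssd", pyramid_levels = 2,
                                    max_iter = 40, tol = 1e-10))
  A <- fit$transform$global$matrix
  expect_lt(max(abs(diag(A) - 1.05)), 0.01)
  expect_lt(max(abs(A[upper.tri(A) | lower.tri(A)])), 0.01)
})

test_that("FFD self-registration stays close to the identity", {
  pair <- two_blob()
  fit <- register_ffd(pair$target, pair$target,
                      reg_config(pyramid_levels = 2, control_spacing0 = 16,
                                 max_iter = 4))
  fld <- transform_to_field(fit$transform, pair$target)
  mean_disp <- mean(sqrt(apply(fld^2, 1:3, sum)))
  expect_lt(mean_disp, 0.2 * 2)  # < 0.2 voxel of 2 mm
  expect_gte(fit$final_metric, fit$initial_metric)
})

test_that("FFD objective history is non-decreasing and bounded in step budget", {
  set.seed(91)
  pair <- two_blob(shift = c(3, 0, 0))
  fit <- register_ffd(pair$target, pair$source,
                      reg_config(pyramid_levels = 2, control_spacing0 = 16,
                                 max_iter = 5))
  budget <- 0
  for (st in fit$states) {
    expect_true(all(diff(st$history[, "objective"]) > 0))
    budget <- budget + st$accepted_step_sum
  }
  # each accepted move changes coefficients by at most the step length
  # (max-norm direction) and displacements are convex combinations of the
  # coefficients, so no component can exceed the accumulated step budget
  fld <- transform_to_field(fit$transform, pair$target)
  expect_lte(max(abs(fld)), budget + 1e-9)
  expect_true(is.finite(jacobian_min(fit$transform, pair$target)))
})

test_that("frozen lattices pass through FFD registration bit-exactly", {
  set.seed(92)
  pair <- two_blob(shift = c(2, 1, 0))
  frozen <- ffd_lattice(c(-20, -20, -20), c(20, 20, 20), c(5, 5, 5),
                        coefficients = array(rnorm(5^3 * 3, 0, 0.5),
                                             c(5, 5, 5, 3)),
                        free_mask = array(FALSE, c(5, 5, 5)))
  init <- composite_transform(locals = list(frozen))
  fit <- register_ffd(pair$target, pair$source,
                      reg_config(pyramid_levels = 1, control_spacing0 = 16,
                                 max_iter = 3, init_transform = init))
  expect_identical(fit$transform$locals[[1]]$coefficients, frozen$coefficients)
})

test_that("multiphase with identical landmark sets degenerates to plain FFD", {
  ph <- make_phantom(seed = 12, size = 32, spacing = 4, global = "none",
                     local_amplitude = 3, roi_amplitude = 0, n_impulses = 0)
  cfg <- reg_config(pyramid_levels = 2, max_iter = 3, control_spacing0 = 24)
  plain <- register_ffd(ph$target, ph$source, cfg)
  mp <- register_multiphase(ph$target, ph$source, ph$roi,
                            ph$landmarks_target, ph$landmarks_target,
                            reg_config(control_spacing0 = 40,
                                       pyramid_levels = 2),
                            cfg)
  f1 <- transform_to_field(plain$transform, ph$target)
  f2 <- transform_to_field(mp$transform, ph$target)
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("registration evaluation report is consistent with the metrics", {
  set.seed(93)
  a <- test_image(c(10, 10, 10))
  ev <- evaluate_registration(a, a)
  expect_equal(ev$cc, 1, tolerance = 1e-12)
  neg <- image3d(-a$voxels, a$origin, a$spacing)
  expect_equal(evaluate_registration(a, neg)$cc, -1, tolerance = 1e-12)

  b <- test_image(c(10, 10, 10))
  labs <- image3d(array(sample(0:2, 1000, TRUE), c(10, 10, 10)))
  ev2 <- evaluate_registration(a, b, labs, labs, transform = composite_transform())
  expect_equal(ev2$cc, pearson_cc(a, b), tolerance = 1e-12)
  expect_equal(ev2$nmi, nmi(a, b), tolerance = 1e-12)
  expect_equal(unname(ev2$dice), c(1, 1))
  expect_equal(ev2$jacobian_min, 1, tolerance = 1e-9)
  expect_error(evaluate_registration(a, test_image(c(9, 10, 10))), "one grid")
})
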
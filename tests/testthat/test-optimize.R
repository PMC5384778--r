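test_that("central finite differences recover analytic gradients", {
  ctr <- c(1, -2, 3)
  obj <- function(x) -sum((x - ctr)^2)
  g <- finite_diff_gradient(obj, c(0, 0, 0), h = 1e-4)
  expect_equal(g, -2 * (c(0, 0, 0) - ctr), tolerance = 1e-6)

  # frozen parameters are never perturbed and get exactly zero gradient
  calls <- new.env(); calls$log <- NULL
  obj2 <- function(x) { calls$log <- rbind(calls$log, x); -sum(x^2) }
  g2 <- finite_diff_gradient(obj2, c(1, 1, 1), h = 0.1,
                             free = c(TRUE, FALSE, TRUE))
  expect_identical(g2[2], 0)
  expect_true(all(calls$log[, 2] == 1))  # param 2 never moved
})

test_that("gradient ascent maximizes a concave quadratic deterministically", {
  ctr <- c(2, -1, 0.5)
  obj <- function(x) -sum((x - ctr)^2)
  fit <- gradient_ascent(obj, c(0, 0, 0),
                         list(max_iter = 200, initial_step = 1,
                              min_step = 1e-6, tol = 1e-12, h = 1e-4))
  expect_lt(max(abs(fit$params - ctr)), 1e-4)
  expect_true(fit$state$converged)
  # monotone history
  expect_true(all(diff(fit$state$history[, "objective"]) > 0))
  # bit-identical trajectory on rerun
  fit2 <- gradient_ascent(obj, c(0, 0, 0),
                          list(max_iter = 200, initial_step = 1,
                               min_step = 1e-6, tol = 1e-12, h = 1e-4))
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$state$history, fit2$state$history)
})

test_that("a non-finite objective at the start is an initialization error", {
  expect_error(gradient_ascent(function(x) NaN, c(0, 0)), "initial parameters")
  expect_error(finite_diff_gradient(function(x) NaN, c(0, 0), h = 0.1),
               "not finite at perturbation")
})

test_that("an objective already at its maximum takes no steps", {
  obj <- function(x) -sum(x^2)
  fit <- gradient_ascent(obj, c(0, 0, 0), list(max_iter = 50, initial_step = 1,
                                               min_step = 1e-4, h = 1e-5))
  expect_identical(fit$state$accepted_steps, 0L)
  expect_true(fit$state$converged)
  expect_identical(fit$params, c(0, 0, 0))
})

test_that("steepest ascent with line search also solves the quadratic", {
  ctr <- c(-3, 4)
  obj <- function(x) -sum((x - ctr)^2)
  fit <- steepest_ascent(obj, c(0, 0), list(max_iter = 100, initial_step = 8,
                                            min_step = 1e-6, tol = 1e-12,
                                            h = 1e-4))
  expect_lt(max(abs(fit$params - ctr)), 1e-3)
})

test_that("translation-only registration of a Gaussian blob recovers the shift", {
  d <- c(24, 24, 24)
  pts <- as.matrix(expand.grid(0:23, 0:23, 0:23)) * 2  # spacing 2 mm
  blobv <- function(c0) exp(-rowSums(sweep(pts, 2, c0)^2) / (2 * 8^2))
  tgt <- image3d(array(blobv(c(23, 23, 23)), d), spacing = c(2, 2, 2))
  src <- image3d(array(blobv(c(26, 21, 23)), d), spacing = c(2, 2, 2))
  # target blob at x maps to source blob at x + (3, -2, 0)
  obj <- function(tr) {
    w <- warp_image(src, rigid_transform(diag(3), c(tr, 0)), tgt)
    -ssd(tgt, w)
  }
  fit <- gradient_ascent(obj, c(0, 0), list(max_iter = 60, initial_step = 1,
                                            min_step = 1e-4, tol = 1e-12,
                                            h = 0.05))
  expect_lt(max(abs(fit$params - c(3, -2))), 0.1)
})

test_that("the local-support NMI gradient equals naive full recomputation", {
  set.seed(61)
  d <- c(32, 32, 32)
  pts <- as.matrix(expand.grid(0:31, 0:31, 0:31)) * 2
  f <- exp(-rowSums(sweep(pts, 2, c(31, 31, 31))^2) / (2 * 14^2)) * 100 +
    sin(pts[, 1] / 7) * 20
  tgt <- image3d(array(f, d), spacing = c(2, 2, 2))
  src <- image3d(array(f + rnorm(prod(d), 0, 2), d), spacing = c(2, 2, 2))
  lat <- ffd_lattice_covering(tgt, 20)
  set.seed(62)
  lat$coefficients <- array(rnorm(prod(lat$shape) * 3, 0, 1.5),
                            c(lat$shape, 3))

  bins <- 32L
  rng_a <- range(tgt$voxels); rng_b <- range(src$voxels)
  wa <- (rng_a[2] - rng_a[1]) / bins; wb <- (rng_b[2] - rng_b[1]) / bins
  pad <- min(src$voxels)
  h <- 0.5
  tgt_bin <- rtfuse:::c_bin_values(as.numeric(tgt$voxels), rng_a[1], wa, bins)

  sample_at <- function(coefvec) {
    l2 <- lat; l2$coefficients <- array(coefvec, c(lat$shape, 3))
    idx <- world_to_voxel(src, pts + ffd_displacement(l2, pts))
    rtfuse:::c_interp(as.numeric(src$voxels), d, idx, 1L, pad)
  }
  nmi_of <- function(coefvec) {
    bb <- rtfuse:::c_bin_values(sample_at(coefvec), rng_b[1], wb, bins)
    e <- rtfuse:::c_hist_entropies(rtfuse:::c_hist_from_bins(tgt_bin, bb, bins))
    (e[1] + e[2]) / e[3]
  }

  coef0 <- as.numeric(lat$coefficients)
  idx0 <- world_to_voxel(src, pts + ffd_displacement(lat, pts))
  base_bin <- rtfuse:::c_bin_values(sample_at(coef0), rng_b[1], wb, bins)
  g_fast <- rtfuse:::c_nmi_grad_ffd(
    as.numeric(src$voxels), d, d, idx0, base_bin, tgt_bin, lat$shape,
    as.logical(lat$free_mask), (tgt$origin - lat$grid_origin) / lat$spacing,
    tgt$spacing / lat$spacing, t(src$direction) / src$spacing,
    bins, rng_b[1], wb, h, pad)

  # naive oracle: full objective recomputation at +/- h for sampled params
  set.seed(63)
  nc <- prod(lat$shape)
  probe <- sample(length(coef0), 30)
  for (q in probe) {
    up <- coef0; up[q] <- up[q] + h
    dn <- coef0; dn[q] <- dn[q] - h
    g_ref <- (nmi_of(up) - nmi_of(dn)) / (2 * h)
    expect_equal(g_fast[q], g_ref, tolerance = 1e-10)
  }
})
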
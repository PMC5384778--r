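test_that("rigid point fit is exact on clean correspondences", {
  set.seed(71)
  P <- landmark_set(paste0("p", 1:6), matrix(rnorm(18, 0, 40), 6, 3))
  expect_lt(max(abs(fit_rigid_points(P, P)$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fit_rigid_points(P, P)$translation)), 1e-12)

  for (rep in 1:20) {
    R <- random_rotation(); tr <- rnorm(3, 0, 30)
    Q <- landmark_set(P$names, P$points %*% t(R) +
                        matrix(tr, 6, 3, byrow = TRUE))
    fit <- fit_rigid_points(P, Q)
    res <- apply_transform_point(fit, P$points) - Q$points
    expect_lt(sqrt(mean(rowSums(res^2))), 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("rigid fit returns a proper rotation even for reflected point sets", {
  set.seed(72)
  P <- landmark_set(paste0("p", 1:5), matrix(rnorm(15, 0, 10), 5, 3))
  Q <- landmark_set(P$names, P$points %*% diag(c(-1, 1, 1)))  # reflection
  fit <- fit_rigid_points(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate point configurations are rejected", {
  line <- landmark_set(c("a", "b", "c"),
                       rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)))
  expect_error(fit_rigid_points(line, line), "collinear")
  two <- landmark_set(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(fit_rigid_points(two, two), "at least 3")
  planar4 <- landmark_set(paste0("p", 1:4),
                          cbind(rnorm(4), rnorm(4), 0))
  expect_error(fit_affine_points(planar4, planar4), "affinely independent")
})

test_that("affine point fit recovers exact and least-squares solutions", {
  set.seed(73)
  P <- landmark_set(paste0("p", 1:8), matrix(rnorm(24, 0, 25), 8, 3))
  expect_lt(max(abs(fit_affine_points(P, P)$matrix - diag(3))), 1e-10)

  A <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)
  tr <- rnorm(3, 0, 10)
  Q <- landmark_set(P$names, P$points %*% t(A) + matrix(tr, 8, 3, byrow = TRUE))
  fit <- fit_affine_points(P, Q)
  expect_lt(max(abs(fit$matrix - A)), 1e-9)
  expect_lt(max(abs(fit$translation - tr)), 1e-8)

  # noisy correspondences: residual equals the normal-equation oracle
  Qn <- landmark_set(P$names, Q$points + matrix(rnorm(24, 0, 0.5), 8, 3))
  fitn <- fit_affine_points(P, Qn)
  X <- cbind(P$points, 1)
  beta <- solve(crossprod(X)) %*% crossprod(X, Qn$points)
  pred_oracle <- X %*% beta
  expect_equal(apply_transform_point(fitn, P$points), unname(pred_oracle),
               tolerance = 1e-9)
})

lffd_fixture <- function(seed = 74, spacing = 10, shape = c(9, 9, 9)) {
  set.seed(seed)
  lat <- ffd_lattice(c(-10, -10, -10), rep(spacing, 3), shape,
                     roi = roi_box(c(10, 10, 10), c(50, 50, 50)))
  P <- landmark_set(paste0("p", 1:12),
                    cbind(runif(12, 15, 45), runif(12, 15, 45),
                          runif(12, 15, 45)))
  list(lat = lat, P = P)
}

test_that("LFFD fit returns zero coefficients when landmarks already match", {
  fx <- lffd_fixture()
  fit <- fit_lffd(fx$P, fx$P, fx$lat, ridge = 1e-6)
  expect_true(all(fit$coefficients == 0))
})

test_that("LFFD fit drives landmark residuals to near zero and keeps frozen
           control points bit-exact", {
  fx <- lffd_fixture()
  Q <- landmark_set(fx$P$names, fx$P$points +
                      matrix(c(5, 0, 0), 12, 3, byrow = TRUE))
  fit <- fit_lffd(fx$P, Q, fx$lat, ridge = 1e-6)
  tre <- landmark_tre(fx$P, Q, composite_transform(locals = list(fit)))
  expect_lt(tre$max, 0.05)
  frozen <- !fit$free_mask
  for (cmp in 1:3)
    expect_identical(fit$coefficients[, , , cmp][frozen],
                     fx$lat$coefficients[, , , cmp][frozen])
})

test_that("LFFD solution equals an independently assembled normal-equation
           oracle", {
  fx <- lffd_fixture(seed = 75)
  set.seed(76)
  Q <- landmark_set(fx$P$names, fx$P$points + matrix(rnorm(36, 0, 2), 12, 3))
  ridge <- 1e-4
  fit <- fit_lffd(fx$P, Q, fx$lat, ridge = ridge)

  # oracle: assemble weights by looping over basis functions per landmark
  lat <- fx$lat
  free <- which(lat$free_mask)
  n <- length(fx$P)
  W <- matrix(0, n, prod(lat$shape))
  for (i in seq_len(n)) {
    g <- (fx$P$points[i, ] - lat$grid_origin) / lat$spacing
    f0 <- floor(g); u <- g - f0
    for (kk in 0:3) for (jj in 0:3) for (ii in 0:3) {
      idx <- (f0[1] - 1 + ii) + lat$shape[1] *
        ((f0[2] - 1 + jj) + lat$shape[2] * (f0[3] - 1 + kk)) + 1
      W[i, idx] <- bspline_basis(ii, u[1]) * bspline_basis(jj, u[2]) *
        bspline_basis(kk, u[3])
    }
  }
  Wf <- W[, free]
  rhs <- Q$points - fx$P$points
  sol <- solve(crossprod(Wf) / n + diag(ridge, length(free)),
               crossprod(Wf, rhs) / n)
  got <- sapply(1:3, function(cmp) fit$coefficients[, , , cmp][free])
  expect_equal(got, unname(sol), tolerance = 1e-8)
})

test_that("LFFD residual is non-increasing as more control points are freed", {
  set.seed(77)
  P <- landmark_set(paste0("p", 1:10),
                    cbind(runif(10, 15, 45), runif(10, 15, 45),
                          runif(10, 15, 45)))
  Q <- landmark_set(P$names, P$points + matrix(rnorm(30, 0, 3), 10, 3))
  resid <- function(roi_half) {
    lat <- ffd_lattice(c(-10, -10, -10), c(10, 10, 10), c(9, 9, 9),
                       roi = roi_box(rep(30 - roi_half, 3),
                                     rep(30 + roi_half, 3)))
    if (sum(lat$free_mask) == 0) return(Inf)
    fit <- fit_lffd(P, Q, lat, ridge = 1e-6)
    mean(landmark_tre(P, Q, composite_transform(locals = list(fit)))$distances^2)
  }
  r <- sapply(c(5, 15, 25), resid)  # nested free sets
  expect_true(all(diff(r) <= 1e-9))
})

test_that("LFFD recovers ground-truth coefficients from dense landmarks", {
  set.seed(78)
  roi <- roi_box(c(15, 15, 15), c(45, 45, 45))
  lat0 <- ffd_lattice(c(-10, -10, -10), c(10, 10, 10), c(9, 9, 9), roi = roi)
  truth <- lat0
  nfree <- sum(truth$free_mask)
  for (cmp in 1:3)
    truth$coefficients[, , , cmp][truth$free_mask] <- rnorm(nfree, 0, 2)
  # many landmarks spread over the support of the free nodes
  p <- as.matrix(expand.grid(seq(8, 52, by = 4.4), seq(8, 52, by = 4.4),
                             seq(8, 52, by = 4.4)))
  P <- landmark_set(paste0("p", seq_len(nrow(p))), p)
  Q <- landmark_set(P$names, p + ffd_displacement(truth, p))
  fit <- fit_lffd(P, Q, lat0, ridge = 1e-10)
  got <- sapply(1:3, function(cmp) fit$coefficients[, , , cmp][fit$free_mask])
  tru <- sapply(1:3, function(cmp) truth$coefficients[, , , cmp][truth$free_mask])
  rel <- sqrt(mean((got - tru)^2)) / sqrt(mean(tru^2))
  expect_lt(rel, 0.01)
})

test_that("landmarks outside the lattice support are refused", {
  fx <- lffd_fixture()
  Pout <- landmark_set("far", matrix(c(500, 500, 500), 1, 3))
  expect_error(fit_lffd(Pout, Pout, fx$lat), "support")
  nofree <- ffd_lattice(c(-10, -10, -10), c(10, 10, 10), c(9, 9, 9),
                        free_mask = array(FALSE, c(9, 9, 9)))
  expect_error(fit_lffd(fx$P, fx$P, nofree), "no free control points")
})
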
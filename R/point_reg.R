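#' Closed-form point-set registration
#'
#' Least-squares fits of a rigid or affine transform mapping a target
#' landmark set `P` onto a corresponding source set `Q` (correspondence is by
#' order). The rigid fit is the orthogonal Procrustes solution with
#' reflections excluded (`det(R) = +1`); the affine fit solves the normal
#' equations. These provide the coarse initialization when a direct
#' intensity-based start would fail.
#'
#' @param P target [landmark_set].
#' @param Q source [landmark_set], same length, corresponding order.
#' @return a [rigid_transform] or [affine_transform] minimizing
#'   `sum_i |T(p_i) - q_i|^2`.
#' @export
fit_rigid_points <- function(P, Q) {
  pq <- check_pairs(P, Q, 3L)
  p <- pq$p; q <- pq$q
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  if (qr(pc)$rank < 2L)
    stop("degenerate configuration: landmarks are collinear")
  s <- svd(crossprod(pc, qc))  # 3x3 covariance P'Q
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

#' @rdname fit_rigid_points
#' @export
fit_affine_points <- function(P, Q) {
  pq <- check_pairs(P, Q, 4L)
  p <- pq$p; q <- pq$q
  X <- cbind(p, 1)
  if (qr(X)$rank < 4L)
    stop("degenerate configuration: landmarks are not affinely independent")
  beta <- solve(crossprod(X), crossprod(X, q))  # 4 x 3
  affine_transform(t(beta[1:3, ]), beta[4, ])
}

check_pairs <- function(P, Q, nmin) {
  stopifnot(inherits(P, "landmark_set"), inherits(Q, "landmark_set"))
  if (length(P) != length(Q))
    stop("landmark sets must have equal size with corresponding order")
  if (length(P) < nmin)
    stop("at least ", nmin, " landmark pairs are required")
  list(p = P$points, q = Q$points)
}

#' Landmark-driven FFD fit (ROI-constrained)
#'
#' Fits the free coefficients of a B-spline lattice so that the transformed
#' target landmarks `p_i + u(p_i)` match their source correspondences `q_i`
#' in the least-squares sense, with a small ridge penalty on the free
#' coefficients to regularize underdetermined systems. The displacement at a
#' point is linear in the coefficients, so the minimizer of
#' `mean_i |p_i + u(p_i) - q_i|^2 + ridge * |Phi_free|^2` is obtained in
#' closed form from the normal equations. Control points outside the free
#' mask (derived from the lattice ROI) keep their coefficients bit-exactly.
#'
#' @param P target landmarks (inside the lattice support).
#' @param Q corresponding source landmarks.
#' @param lat an [ffd_lattice]; typically built with a ROI so only control
#'   points near the region of interest move.
#' @param ridge ridge weight (per squared mm of coefficient).
#' @return the fitted [ffd_lattice].
#' @export
fit_lffd <- function(P, Q, lat, ridge = 1e-6) {
  pq <- check_pairs(P, Q, 1L)
  stopifnot(inherits(lat, "ffd_lattice"))
  free <- which(lat$free_mask)
  if (length(free) == 0L) stop("lattice has no free control points")
  n <- nrow(pq$p)
  W <- lffd_design_matrix(lat, pq$p)
  if (!all(is.finite(W)))
    stop("landmarks outside the lattice support domain")
  sup <- attr(W, "supported")
  if (!all(sup)) stop("landmarks outside the lattice support domain")
  # residual displacement still to be explained after the frozen part
  r <- pq$q - pq$p - ffd_displacement(lat, pq$p)
  Wf <- W[, free, drop = FALSE]
  A <- crossprod(Wf) / n + diag(ridge, length(free))
  rhs <- crossprod(Wf, r) / n
  sol <- solve(A, rhs)  # |free| x 3
  coef <- lat$coefficients
  nc <- prod(lat$shape)
  for (cmp in 1:3) coef[free + (cmp - 1) * nc] <- coef[free + (cmp - 1) * nc] + sol[, cmp]
  ffd_lattice(lat$grid_origin, lat$spacing, lat$shape, coefficients = coef,
              roi = lat$roi, free_mask = lat$free_mask,
              strict_piecewise = lat$strict_piecewise)
}

# N x (number of control points) matrix of tensor-product basis weights of
# each control point at each landmark. Rows for unsupported points are
# flagged via the "supported" attribute.
lffd_design_matrix <- function(lat, p) {
  n <- nrow(p)
  nc <- prod(lat$shape)
  W <- matrix(0, n, nc)
  supported <- rep(TRUE, n)
  for (i in seq_len(n)) {
    g <- (p[i, ] - lat$grid_origin) / lat$spacing
    f <- floor(g)
    if (any(f - 1 < 0) || any(f + 2 > lat$shape - 1)) {
      supported[i] <- FALSE
      next
    }
    u <- g - f
    wx <- vapply(0:3, bspline_basis, 0, t = u[1])
    wy <- vapply(0:3, bspline_basis, 0, t = u[2])
    wz <- vapply(0:3, bspline_basis, 0, t = u[3])
    for (kk in 0:3) for (jj in 0:3) for (ii in 0:3) {
      ci <- f[1] - 1 + ii; cj <- f[2] - 1 + jj; ck <- f[3] - 1 + kk
      idx <- ci + lat$shape[1] * (cj + lat$shape[2] * ck) + 1
      W[i, idx] <- W[i, idx] + wx[ii + 1] * wy[jj + 1] * wz[kk + 1]
    }
  }
  attr(W, "supported") <- supported
  W
}

#' Landmark target registration error
#'
#' Mean Euclidean distance between transformed target landmarks and their
#' source correspondences.
#'
#' @inheritParams fit_lffd
#' @param t a transform (or NULL for the identity).
#' @return named list with `mean`, `max` and per-landmark `distances` (mm).
#' @export
landmark_tre <- function(P, Q, t = NULL) {
  pq <- check_pairs(P, Q, 1L)
  tp <- apply_transform_point(t, pq$p)
  d <- sqrt(rowSums((tp - pq$q)^2))
  list(mean = mean(d), max = max(d), distances = d)
}
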
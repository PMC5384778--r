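# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with naive loops so they share no code with the package
# internals they check.

# naive tensor-product FFD displacement at a single world point
oracle_ffd_disp <- function(lat, p) {
  bsp <- function(l, t) switch(l + 1L,
    (1 - t)^3 / 6,
    (3 * t^3 - 6 * t^2 + 4) / 6,
    (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
    t^3 / 6)
  g <- (p - lat$grid_origin) / lat$spacing
  f <- floor(g)
  if (any(f - 1 < 0) || any(f + 2 > lat$shape - 1)) return(c(0, 0, 0))
  u <- g - f
  acc <- c(0, 0, 0)
  for (k in 0:3) for (j in 0:3) for (i in 0:3) {
    w <- bsp(i, u[1]) * bsp(j, u[2]) * bsp(k, u[3])
    acc <- acc + w * lat$coefficients[f[1] + i, f[2] + j, f[3] + k, ]
  }
  acc
}

# per-voxel neighbourhood sort median with edge replication
oracle_median <- function(vox, r) {
  d <- dim(vox)
  out <- array(0, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    xs <- pmin(pmax(x + (-r):r, 1), d[1])
    ys <- pmin(pmax(y + (-r):r, 1), d[2])
    zs <- pmin(pmax(z + (-r):r, 1), d[3])
    out[x, y, z] <- median(vox[xs, ys, zs])
  }
  out
}

# nearest-index resampling oracle: round the continuous index, pad outside
# the closed voxel-centre hull
oracle_nearest <- function(src, ref, pad) {
  d <- dim(src$voxels)
  out <- array(pad, dim(ref$voxels))
  pts <- rtfuse::voxel_to_world(ref, as.matrix(expand.grid(
    0:(dim(ref$voxels)[1] - 1), 0:(dim(ref$voxels)[2] - 1),
    0:(dim(ref$voxels)[3] - 1))))
  idx <- rtfuse::world_to_voxel(src, pts)
  for (n in seq_len(nrow(idx))) {
    if (any(idx[n, ] < 0) || any(idx[n, ] > d - 1)) next
    r <- floor(idx[n, ] + 0.5) + 1
    out[n] <- src$voxels[r[1], r[2], r[3]]
  }
  out
}

# per-voxel joint-histogram binning oracle (equal-width bins, hard clamp)
oracle_joint_hist <- function(a, b, bins) {
  va <- as.numeric(a); vb <- as.numeric(b)
  keep <- is.finite(va) & is.finite(vb)
  va <- va[keep]; vb <- vb[keep]
  ra <- range(va); rb <- range(vb)
  wa <- (ra[2] - ra[1]) / bins; wb <- (rb[2] - rb[1]) / bins
  if (wa <= 0) wa <- 1
  if (wb <= 0) wb <- 1
  h <- matrix(0, bins, bins)
  for (n in seq_along(va)) {
    i <- min(max(floor((va[n] - ra[1]) / wa), 0), bins - 1) + 1
    j <- min(max(floor((vb[n] - rb[1]) / wb), 0), bins - 1) + 1
    h[i, j] <- h[i, j] + 1
  }
  h
}

# random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small test image helpers
test_image <- function(d = c(12, 12, 12), origin = c(0, 0, 0),
                       spacing = c(1, 1, 1), vals = NULL) {
  if (is.null(vals)) vals <- array(stats::runif(prod(d)), d)
  rtfuse::image3d(array(vals, d), origin = origin, spacing = spacing)
}
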
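#' Joint intensity histogram of two images on a common grid
#'
#' Equal-width hard binning over each image's `[min, max]` (restricted to the
#' mask); voxels where either value is non-finite are excluded. The histogram
#' is the basis of the information-theoretic similarity metrics.
#'
#' @param a,b [image3d] objects on the same grid.
#' @param bins number of bins per axis (>= 2).
#' @param mask optional logical array (or 0/1 [image3d]) selecting voxels.
#' @param range_a,range_b optional frozen `c(lo, hi)` intensity ranges; used
#'   by the registration engine to keep the objective stationary while the
#'   moving image changes. Values outside a frozen range clamp into the end
#'   bins.
#' @return object of class `joint_histogram` with fields `counts`
#'   (bins x bins, rows = a), `bin_edges_a`, `bin_edges_b`, `n_samples`.
#' @export
joint_histogram <- function(a, b, bins = 64, mask = NULL,
                            range_a = NULL, range_b = NULL) {
  vals <- metric_values(a, b, mask)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  if (is.null(range_a)) range_a <- range(vals$a, finite = TRUE)
  if (is.null(range_b)) range_b <- range(vals$b, finite = TRUE)
  wa <- bin_width(range_a, bins); wb <- bin_width(range_b, bins)
  ba <- c_bin_values(vals$a, range_a[1], wa, bins)
  bb <- c_bin_values(vals$b, range_b[1], wb, bins)
  counts <- c_hist_from_bins(ba, bb, bins)
  structure(list(counts = counts,
                 bin_edges_a = seq(range_a[1], by = wa, length.out = bins + 1L),
                 bin_edges_b = seq(range_b[1], by = wb, length.out = bins + 1L),
                 n_samples = sum(counts)),
            class = "joint_histogram")
}

bin_width <- function(rng, bins) {
  w <- (rng[2] - rng[1]) / bins
  if (w <= 0) w <- 1  # constant image: everything lands in bin 0
  w
}

metric_values <- function(a, b, mask = NULL) {
  stopifnot(is_image3d(a), is_image3d(b))
  if (!same_grid(a, b)) stop("images must share a grid for similarity metrics")
  va <- as.numeric(a$voxels); vb <- as.numeric(b$voxels)
  if (!is.null(mask)) {
    m <- if (is_image3d(mask)) mask$voxels != 0 else as.logical(mask)
    if (length(m) != length(va)) stop("mask size does not match images")
    va <- va[m]; vb <- vb[m]
  }
  keep <- is.finite(va) & is.finite(vb)
  list(a = va[keep], b = vb[keep])
}

hist_entropies <- function(h) {
  e <- c_hist_entropies(h$counts)
  list(Ha = e[1], Hb = e[2], Hab = e[3])
}

#' Similarity metrics between two images
#'
#' All metrics operate voxelwise on a shared grid, optionally under a mask.
#' `nmi` is normalized mutual information `(H(A) + H(B)) / H(A,B)` with
#' entropies in nats from the hard-binned joint histogram; it lies in
#' `[1, 2]`, reaching 2 when the images determine each other and 1 under
#' independence. `mutual_information` is `H(A) + H(B) - H(A,B)`,
#' `joint_entropy` is `H(A,B)`, `ssd` the mean squared intensity difference,
#' `pearson_cc` the Pearson correlation coefficient, and
#' `correlation_ratio` the eta-squared of B explained by binned A.
#'
#' @inheritParams joint_histogram
#' @return a single numeric score.
#' @export
nmi <- function(a, b, bins = 64, mask = NULL, range_a = NULL, range_b = NULL) {
  h <- joint_histogram(a, b, bins, mask, range_a, range_b)
  e <- hist_entropies(h)
  if (e$Hab == 0) {
    if (e$Ha == 0 && e$Hb == 0)
      stop("NMI undefined: both images are constant over the mask")
    stop("NMI undefined: zero joint entropy")
  }
  (e$Ha + e$Hb) / e$Hab
}

#' @rdname nmi
#' @export
mutual_information <- function(a, b, bins = 64, mask = NULL,
                               range_a = NULL, range_b = NULL) {
  h <- joint_histogram(a, b, bins, mask, range_a, range_b)
  e <- hist_entropies(h)
  e$Ha + e$Hb - e$Hab
}

#' @rdname nmi
#' @export
joint_entropy <- function(a, b, bins = 64, mask = NULL,
                          range_a = NULL, range_b = NULL) {
  hist_entropies(joint_histogram(a, b, bins, mask, range_a, range_b))$Hab
}

#' @rdname nmi
#' @export
ssd <- function(a, b, mask = NULL) {
  v <- metric_values(a, b, mask)
  mean((v$a - v$b)^2)
}

#' @rdname nmi
#' @export
pearson_cc <- function(a, b, mask = NULL) {
  v <- metric_values(a, b, mask)
  if (stats::sd(v$a) == 0 || stats::sd(v$b) == 0)
    stop("correlation undefined: constant image over the mask")
  stats::cor(v$a, v$b)
}

#' @rdname nmi
#' @export
correlation_ratio <- function(a, b, bins = 64, mask = NULL) {
  v <- metric_values(a, b, mask)
  if (stats::var(v$b) == 0)
    stop("correlation ratio undefined: constant image B over the mask")
  rng <- range(v$a)
  w <- bin_width(rng, bins)
  ba <- c_bin_values(v$a, rng[1], w, as.integer(bins))
  grp_mean <- tapply(v$b, ba, mean)
  grp_n <- tapply(v$b, ba, length)
  mu <- mean(v$b)
  between <- sum(grp_n * (grp_mean - mu)^2) / length(v$b)
  between / (mean((v$b - mu)^2))
}

# Internal: metric dispatcher with "larger is better" polarity (SSD and joint
# entropy are negated so a single maximizer drives every metric).
metric_fn <- function(metric = c("nmi", "mi", "ssd", "cc", "je", "cr"),
                      bins = 64) {
  metric <- match.arg(metric)
  switch(metric,
    nmi = function(a, b, mask = NULL, range_a = NULL, range_b = NULL)
      nmi(a, b, bins, mask, range_a, range_b),
    mi = function(a, b, mask = NULL, range_a = NULL, range_b = NULL)
      mutual_information(a, b, bins, mask, range_a, range_b),
    je = function(a, b, mask = NULL, range_a = NULL, range_b = NULL)
      -joint_entropy(a, b, bins, mask, range_a, range_b),
    ssd = function(a, b, mask = NULL, range_a = NULL, range_b = NULL)
      -ssd(a, b, mask),
    cc = function(a, b, mask = NULL, range_a = NULL, range_b = NULL)
      pearson_cc(a, b, mask),
    cr = function(a, b, mask = NULL, range_a = NULL, range_b = NULL)
      correlation_ratio(a, b, bins, mask))
}
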
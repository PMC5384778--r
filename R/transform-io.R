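# Transform container I/O. On-disk format: JSON (".tfm.json") holding the
# global part as a 4x4 row-major matrix and each lattice's geometry plus its
# coefficients as base64-encoded little-endian float64, x-index fastest and
# displacement component slowest (the natural array order), so round-trips
# are bit-exact.

#' Read and write composite transforms
#'
#' @param t transform to save (anything accepted by the composite family).
#' @param path JSON file path (conventionally `.tfm.json`).
#' @return [read_transform()] returns a [composite_transform].
#' @export
write_transform <- function(t, path) {
  t <- as_composite(t)
  g <- diag(4)
  gtype <- "identity"
  if (!is.null(t$global)) {
    g[1:3, 1:3] <- linear_matrix(t$global)
    g[1:3, 4] <- t$global$translation
    gtype <- if (inherits(t$global, "rigid_transform")) "rigid" else "affine"
  }
  lat_json <- lapply(t$locals, function(lat) {
    list(origin = lat$grid_origin, spacing = lat$spacing, shape = lat$shape,
         strict_piecewise = lat$strict_piecewise,
         roi = if (is.null(lat$roi)) NULL
               else list(lower = lat$roi$lower, upper = lat$roi$upper),
         free_mask = as.logical(lat$free_mask),
         coefficients = jsonlite::base64_enc(
           writeBin(as.numeric(lat$coefficients), raw(), size = 8,
                    endian = "little")))
  })
  obj <- list(format = "rtfuse-transform-v1", global_type = gtype,
              global = as.vector(t(g)), lattices = lat_json)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("no such transform file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("format", "global_type", "global", "lattices"))
    if (is.null(obj[[field]]))
      stop("transform file missing field '", field, "': ", path)
  if (!identical(obj$format, "rtfuse-transform-v1"))
    stop("unrecognized transform format '", obj$format, "' in ", path)
  g <- matrix(as.numeric(unlist(obj$global)), 4, 4, byrow = TRUE)
  global <- switch(obj$global_type,
    identity = NULL,
    rigid = rigid_transform(g[1:3, 1:3], g[1:3, 4]),
    affine = affine_transform(g[1:3, 1:3], g[1:3, 4]),
    stop("unknown global_type '", obj$global_type, "' in ", path))
  locals <- lapply(seq_along(obj$lattices), function(i) {
    l <- obj$lattices[[i]]
    for (field in c("origin", "spacing", "shape", "coefficients"))
      if (is.null(l[[field]]))
        stop("lattice ", i, " missing field '", field, "' in ", path)
    shape <- as.integer(unlist(l$shape))
    coef <- readBin(jsonlite::base64_dec(unlist(l$coefficients)[1]), "double",
                    n = prod(shape) * 3, size = 8, endian = "little")
    roi <- NULL
    if (!is.null(l$roi) && length(unlist(l$roi)))
      roi <- roi_box(unlist(l$roi$lower), unlist(l$roi$upper))
    ffd_lattice(unlist(l$origin), unlist(l$spacing), shape,
                coefficients = array(coef, c(shape, 3)), roi = roi,
                free_mask = array(as.logical(unlist(l$free_mask)), shape),
                strict_piecewise = isTRUE(unlist(l$strict_piecewise)))
  })
  composite_transform(global = global, locals = locals)
}

#' Export the dense displacement field as a vector NIfTI volume
#'
#' Writes a 4D NIfTI (last dimension = 3) of world displacements in mm, LPS,
#' sampled on the reference grid.
#'
#' @inheritParams warp_image
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_displacement_field <- function(t, ref, path) {
  fld <- transform_to_field(t, ref)
  lin <- ref$direction %*% diag(ref$spacing)
  aff <- rbind(cbind(ras_to_lps %*% lin, as.numeric(ras_to_lps %*% ref$origin)),
               c(0, 0, 0, 1))
  nim <- RNifti::asNifti(fld)
  nim <- RNifti::`sform<-`(nim, structure(aff, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(NULL)
}

# Dyadic refinement of a cubic B-spline lattice: spacing halves, the origin is
# kept, and the classical subdivision masks reproduce the same displacement
# field (even node: (c[i-1] + 6 c[i] + c[i+1])/8; odd node: (c[i] + c[i+1])/2),
# applied per axis. Out-of-range source coefficients count as zero.
subdivide_lattice <- function(lat) {
  coef <- lat$coefficients
  for (axis in 1:3) {
    d <- dim(coef)
    n <- d[axis]
    n2 <- 2L * n - 1L
    perm <- c(axis, setdiff(seq_along(d), axis))
    a <- aperm(coef, perm)
    m <- matrix(a, n, prod(d[-axis]))
    pad <- rbind(0, m, 0)                     # rows 1..n at offset +1
    even <- (pad[1:n, , drop = FALSE] + 6 * pad[2:(n + 1), , drop = FALSE] +
               pad[3:(n + 2), , drop = FALSE]) / 8
    odd <- (m[1:(n - 1), , drop = FALSE] + m[2:n, , drop = FALSE]) / 2
    out <- matrix(0, n2, ncol(m))
    out[seq(1, n2, by = 2), ] <- even
    out[seq(2, n2 - 1, by = 2), ] <- odd
    d2 <- d; d2[axis] <- n2
    coef <- aperm(array(out, c(n2, d[-axis])), order(perm))
  }
  ffd_lattice(lat$grid_origin, lat$spacing / 2, 2L * lat$shape - 1L,
              coefficients = coef, roi = lat$roi,
              strict_piecewise = lat$strict_piecewise)
}
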
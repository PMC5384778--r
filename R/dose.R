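#' Dose grid on its own geometry
#'
#' A 3D array of absorbed dose in Gy together with image geometry, plus a
#' fraction label identifying the treatment it belongs to.
#'
#' @param values numeric 3D array of dose (Gy), finite and non-negative.
#' @inheritParams image3d
#' @param fraction_label text label of the treatment fraction.
#' @return an object of class `dose_grid` (also an [image3d]).
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      direction = diag(3), fraction_label = "") {
  img <- image3d(values, origin, spacing, direction)
  if (any(!is.finite(img$voxels))) stop("dose values must be finite")
  if (any(img$voxels < 0)) stop("dose values must be non-negative")
  img$fraction_label <- as.character(fraction_label)
  class(img) <- c("dose_grid", class(img))
  img
}

as_dose_grid <- function(img, fraction_label = "") {
  dose_grid(img$voxels, img$origin, img$spacing, img$direction, fraction_label)
}

#' Read a dose grid
#'
#' Reads DICOM RTDOSE (pixel values multiplied by the dose-grid scaling
#' factor, per-frame offsets honored) or a NIfTI dose volume. Results are in
#' Gy on the file's native geometry.
#'
#' @param path an RTDOSE `.dcm` file or a `.nii`/`.nii.gz` volume.
#' @param fraction_label label attached to the returned grid.
#' @return a [dose_grid].
#' @export
read_dose <- function(path, fraction_label = "") {
  if (!file.exists(path)) stop("no such dose file: ", path)
  if (grepl("\\.nii(\\.gz)?$", tolower(path)))
    return(as_dose_grid(read_nifti_volume(path), fraction_label))
  elems <- parse_dicom_file(path)
  modality <- dcm_str(elems, 0x0008, 0x0060)
  if (!is.null(modality) && modality != "RTDOSE")
    stop("expected an RTDOSE object, found modality '", modality, "': ", path)
  g <- dcm_plane_geometry(elems, path)
  scaling <- dcm_numeric(elems, 0x3004, 0x000e)
  if (is.null(scaling)) stop("RTDOSE missing DoseGridScaling: ", path)
  nframes <- dcm_numeric(elems, 0x0028, 0x0008)
  if (is.null(nframes)) nframes <- 1
  nframes <- as.integer(nframes)
  offsets <- dcm_numeric(elems, 0x3004, 0x000c)
  if (nframes > 1L) {
    if (is.null(offsets)) stop("multi-frame RTDOSE missing GridFrameOffsetVector: ", path)
    if (length(offsets) != nframes)
      stop("GridFrameOffsetVector length does not match NumberOfFrames: ", path)
    dz <- diff(offsets)
    if (any(dz <= 0) || max(dz) - min(dz) > 1e-3 * mean(dz))
      stop("RTDOSE frame offsets must be uniformly increasing: ", path)
    sp_z <- mean(dz)
  } else sp_z <- 1
  bits <- dcm_u16(elems, 0x0028, 0x0100)
  if (is.null(bits)) bits <- 32L
  px <- dcm_pixels(elems, bits, signed = FALSE, path)
  if (any(px < 0)) stop("negative stored dose values in ", path)
  vals <- array(0, c(g$cols, g$rows, nframes))
  per <- g$cols * g$rows
  for (k in seq_len(nframes))
    vals[, , k] <- matrix(px[((k - 1) * per + 1):(k * per)], g$cols, g$rows)
  off0 <- if (is.null(offsets)) 0 else offsets[1]
  dose_grid(vals * scaling,
            origin = g$ipp + off0 * g$normal,
            spacing = c(g$sp_x, g$sp_y, sp_z),
            direction = cbind(g$ex, g$ey, g$normal),
            fraction_label = fraction_label)
}

#' @rdname read_dose
#' @param d a [dose_grid].
#' @export
write_dose <- function(d, path) {
  write_nifti_volume(d, path)
}

#' Warp a dose grid through a registration transform
#'
#' Pull-back resampling of a fraction dose onto the reference grid: the
#' transform maps reference-frame points into the dose's frame and the dose
#' is linearly interpolated there. Points outside the dose footprint
#' receive 0 Gy. This is pointwise resampling of physical dose; no
#' energy/mass-preserving correction is applied.
#'
#' @param d a [dose_grid] (e.g. an HDR-BT fraction dose).
#' @param t transform mapping reference-frame points into the dose frame.
#' @param ref [image3d] (or dose grid) defining the reference geometry.
#' @return a [dose_grid] on the reference geometry.
#' @export
warp_dose <- function(d, t, ref) {
  stopifnot(inherits(d, "dose_grid"))
  w <- warp_image(d, t, ref, interp = "linear", pad_value = 0)
  dose_grid(w$voxels, w$origin, w$spacing, w$direction, d$fraction_label)
}

#' Accumulate fraction doses onto a reference dose
#'
#' Voxelwise sum `D_total(x) = D_ref(x) + sum_i D_i'(x)` of the reference
#' dose and the already-warped fraction doses; all grids must share the
#' reference geometry exactly (no silent resampling). Summation order is the
#' input order.
#'
#' @param reference the reference [dose_grid].
#' @param warped list of [dose_grid]s already warped onto the reference grid.
#' @return the accumulated [dose_grid].
#' @export
accumulate_dose <- function(reference, warped = list()) {
  stopifnot(inherits(reference, "dose_grid"))
  if (inherits(warped, "dose_grid")) warped <- list(warped)
  total <- reference$voxels
  for (w in warped) {
    stopifnot(inherits(w, "dose_grid"))
    if (!same_grid(reference, w))
      stop("dose grids must share the reference geometry; warp first")
    total <- total + w$voxels
  }
  dose_grid(total, reference$origin, reference$spacing, reference$direction,
            "accumulated")
}

#' Per-label dose summary
#'
#' @param total a [dose_grid].
#' @param labels integer label [image3d] on the same grid; label 0 is
#'   background and labels absent from the volume are omitted.
#' @return data frame with columns `label`, `mean_gy`, `max_gy`, `voxels`.
#' @export
dose_report <- function(total, labels) {
  stopifnot(inherits(total, "dose_grid"), is_image3d(labels))
  if (!same_grid(total, labels))
    stop("labels must share the dose grid geometry")
  labs <- sort(setdiff(unique(as.vector(labels$voxels)), 0))
  rows <- lapply(labs, function(l) {
    v <- total$voxels[labels$voxels == l]
    data.frame(label = l, mean_gy = mean(v), max_gy = max(v),
               voxels = length(v))
  })
  if (length(rows) == 0L)
    return(data.frame(label = numeric(0), mean_gy = numeric(0),
                      max_gy = numeric(0), voxels = integer(0)))
  do.call(rbind, rows)
}
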
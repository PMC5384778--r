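# Tiny synthetic DICOM writer (explicit VR little endian) used to exercise
# the CT-series and RTDOSE readers. Only the elements the reader consumes
# are emitted.

dcm_elem <- function(group, element, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    if (length(payload) %% 2 == 1) payload <- c(payload, charToRaw(" "))
  }
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, raw(2),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(head, writeBin(as.integer(length(payload)), raw(), size = 2,
                     endian = "little"), payload)
  }
}

dcm_ds <- function(x) paste(format(x, digits = 10, trim = TRUE), collapse = "\\")
dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

# one CT slice: int16 pixels with rescale slope/intercept
write_test_ct_slice <- function(path, pixels_int16, ipp,
                                iop = c(1, 0, 0, 0, 1, 0),
                                pixel_spacing_rc = c(1, 1),
                                slope = 1, intercept = 0) {
  rows <- ncol(pixels_int16)  # DICOM rows = y, matrix given [x, y]
  cols <- nrow(pixels_int16)
  px <- writeBin(as.integer(as.vector(pixels_int16)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0020, 0x0032, "DS", dcm_ds(ipp)),
    dcm_elem(0x0020, 0x0037, "DS", dcm_ds(iop)),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(cols)),
    dcm_elem(0x0028, 0x0030, "DS", dcm_ds(pixel_spacing_rc)),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(1)),
    dcm_elem(0x0028, 0x1052, "DS", dcm_ds(intercept)),
    dcm_elem(0x0028, 0x1053, "DS", dcm_ds(slope)),
    dcm_elem(0x7fe0, 0x0010, "OW", px))
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}

write_test_ct_series <- function(dir, vox, spacing, origin = c(0, 0, 0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vox)
  for (k in seq_len(d[3]))
    write_test_ct_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                        matrix(as.integer(vox[, , k]), d[1], d[2]),
                        ipp = c(origin[1], origin[2],
                                origin[3] + (k - 1) * spacing[3]),
                        pixel_spacing_rc = c(spacing[2], spacing[1]))
  invisible(dir)
}

# multi-frame RTDOSE: uint32 payload scaled by DoseGridScaling
write_test_rtdose <- function(path, counts, scaling, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  d <- dim(counts)
  px <- writeBin(as.integer(as.vector(counts)), raw(), size = 4,
                 endian = "little")
  body <- c(
    dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_elem(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_elem(0x0020, 0x0032, "DS", dcm_ds(origin)),
    dcm_elem(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_elem(0x0028, 0x0008, "IS", as.character(d[3])),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(d[2])),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(d[1])),
    dcm_elem(0x0028, 0x0030, "DS", dcm_ds(c(spacing[2], spacing[1]))),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(32)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(0)),
    dcm_elem(0x3004, 0x000c, "DS", dcm_ds((seq_len(d[3]) - 1) * spacing[3])),
    dcm_elem(0x3004, 0x000e, "DS", dcm_ds(scaling)),
    dcm_elem(0x7fe0, 0x0010, "OW", px))
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}
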
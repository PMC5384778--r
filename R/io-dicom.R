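# Minimal DICOM reading: enough of the explicit-VR little-endian encoding to
# load CT slice series and RTDOSE grids (geometry, rescale/scaling, pixel
# data). Sequences with undefined lengths and compressed transfer syntaxes
# are rejected up front. A matching synthetic writer lives in the test
# helpers; real-world DICOM variability beyond this profile is out of scope.

dcm_tag <- function(group, element) sprintf("%04x%04x", group, element)

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM element not supported: ", path)
    val_at <- pos + hdr
    if (val_at + len - 1L > n) stop("truncated DICOM element in ", path)
    tag <- dcm_tag(group, element)
    elems[[tag]] <- list(vr = vr,
                         raw = if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0))
    pos <- val_at + len
  }
  ts <- dcm_str(elems, 0x0002, 0x0010)
  if (!is.null(ts) && !(ts %in% c("1.2.840.10008.1.2.1")))
    stop("unsupported DICOM transfer syntax '", ts, "' in ", path)
  elems
}

dcm_str <- function(elems, group, element) {
  e <- elems[[dcm_tag(group, element)]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
}

dcm_numeric <- function(elems, group, element) {
  s <- dcm_str(elems, group, element)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_u16 <- function(elems, group, element) {
  e <- elems[[dcm_tag(group, element)]]
  if (is.null(e)) return(NULL)
  readBin(e$raw, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
}

dcm_pixels <- function(elems, bits, signed, path) {
  e <- elems[[dcm_tag(0x7fe0, 0x0010)]]
  if (is.null(e)) stop("DICOM file has no pixel data: ", path)
  if (bits == 16) {
    readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2,
            signed = signed, endian = "little")
  } else if (bits == 32) {
    v <- readBin(e$raw, "integer", n = length(e$raw) / 4, size = 4,
                 endian = "little")
    if (!signed && any(v < 0))
      stop("32-bit unsigned pixel values exceed supported range in ", path)
    v
  } else stop("unsupported BitsAllocated ", bits, " in ", path)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Geometry common to CT slices and RTDOSE frames.
dcm_plane_geometry <- function(elems, path) {
  ipp <- dcm_numeric(elems, 0x0020, 0x0032)
  iop <- dcm_numeric(elems, 0x0020, 0x0037)
  ps <- dcm_numeric(elems, 0x0028, 0x0030)
  rows <- dcm_u16(elems, 0x0028, 0x0010)
  cols <- dcm_u16(elems, 0x0028, 0x0011)
  if (is.null(ipp) || is.null(iop) || is.null(ps) || is.null(rows) || is.null(cols))
    stop("DICOM file missing geometry (position/orientation/spacing/size): ", path)
  list(ipp = ipp, ex = iop[1:3], ey = iop[4:6], normal = cross3(iop[1:3], iop[4:6]),
       sp_x = ps[2], sp_y = ps[1], rows = rows, cols = cols)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 1L) stop("empty DICOM series directory: ", dir)
  slices <- lapply(files, function(f) {
    elems <- parse_dicom_file(f)
    g <- dcm_plane_geometry(elems, f)
    bits <- dcm_u16(elems, 0x0028, 0x0100)
    if (is.null(bits)) bits <- 16L
    pr <- dcm_u16(elems, 0x0028, 0x0103)
    signed <- !is.null(pr) && pr == 1L
    slope <- dcm_numeric(elems, 0x0028, 0x1053); if (is.null(slope)) slope <- 1
    inter <- dcm_numeric(elems, 0x0028, 0x1052); if (is.null(inter)) inter <- 0
    px <- dcm_pixels(elems, bits, signed, f) * slope + inter
    list(g = g, px = px)
  })
  g1 <- slices[[1]]$g
  for (s in slices) {
    if (max(abs(s$g$ex - g1$ex)) > 1e-6 || max(abs(s$g$ey - g1$ey)) > 1e-6)
      stop("DICOM series has inconsistent slice orientations: ", dir)
    if (abs(s$g$sp_x - g1$sp_x) > 1e-6 || abs(s$g$sp_y - g1$sp_y) > 1e-6)
      stop("DICOM series has inconsistent pixel spacing: ", dir)
    if (s$g$rows != g1$rows || s$g$cols != g1$cols)
      stop("DICOM series has inconsistent slice sizes: ", dir)
  }
  z <- vapply(slices, function(s) sum(s$g$ipp * g1$normal), 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("DICOM series contains duplicate slice positions: ", dir)
    if (max(dz) - min(dz) > 1e-3 * mean(dz))
      stop("DICOM series has inconsistent slice spacing: ", dir)
    sp_z <- mean(dz)
  } else sp_z <- 1
  vox <- array(0, c(g1$cols, g1$rows, nz))
  for (k in seq_len(nz))
    vox[, , k] <- matrix(slices[[k]]$px, nrow = g1$cols, ncol = g1$rows)
  image3d(vox, origin = slices[[1]]$g$ipp,
          spacing = c(g1$sp_x, g1$sp_y, sp_z),
          direction = cbind(g1$ex, g1$ey, g1$normal))
}
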
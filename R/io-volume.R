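#' Read and write 3D volumes
#'
#' Supported formats: NIfTI-1 (`.nii` / `.nii.gz`), MetaImage (`.mha`, or
#' `.mhd` with a raw sidecar), and DICOM CT series (a directory of slice
#' files). All geometry is converted to the single internal world frame, the
#' DICOM patient frame (LPS, mm): NIfTI affines, which are RAS by convention,
#' are sign-flipped in x and y on read and re-converted on write.
#'
#' @param path file path (or directory for a DICOM series).
#' @return [read_volume()] returns an [image3d]; [write_volume()] is called
#'   for its side effect and the output format follows the file extension.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such volume file: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_volume(path))
  if (grepl("\\.(mha|mhd)$", lp)) return(read_metaimage(path))
  stop("unsupported volume format (expect .nii/.nii.gz/.mha/.mhd or DICOM dir): ", path)
}

#' @rdname read_volume
#' @param img an [image3d].
#' @export
write_volume <- function(img, path) {
  stopifnot(is_image3d(img))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(write_nifti_volume(img, path))
  if (grepl("\\.(mha|mhd)$", lp)) return(write_metaimage(img, path))
  stop("unsupported output format: ", path)
}

## --- NIfTI (RAS on disk, LPS internally) -----------------------------------

ras_to_lps <- diag(c(-1, -1, 1))

read_nifti_volume <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  nd <- length(dim(arr))
  if (nd == 4 && dim(arr)[4] == 1L) { arr <- arr[, , , 1, drop = TRUE]; nd <- 3 }
  if (nd != 3) stop("only 3D NIfTI volumes are supported: ", path)
  aff <- RNifti::xform(nim, useQuaternionFirst = FALSE)
  lin <- ras_to_lps %*% aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing <= 0)) stop("degenerate NIfTI affine in ", path)
  direction <- sweep(lin, 2, spacing, "/")
  origin <- as.numeric(ras_to_lps %*% aff[1:3, 4])
  image3d(arr, origin = origin, spacing = spacing, direction = direction)
}

write_nifti_volume <- function(img, path) {
  lin <- img$direction %*% diag(img$spacing)
  aff <- rbind(cbind(ras_to_lps %*% lin, as.numeric(ras_to_lps %*% img$origin)),
               c(0, 0, 0, 1))
  nim <- RNifti::asNifti(img$voxels)
  nim <- RNifti::`sform<-`(nim, structure(aff, code = 2L))
  nim <- RNifti::`qform<-`(nim, structure(aff, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(NULL)
}

## --- MetaImage --------------------------------------------------------------
## ITK MetaImage: ASCII header + raw little-endian voxel block; world frame is
## LPS natively, so geometry passes through unchanged. Written here directly
## (header + writeBin) since no installed package reads the format.

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("MetaImage header ended before ElementDataFile: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line in ", path, ": ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementSpacing")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("MetaImage header missing ", paste(miss, collapse = ", "), ": ", path)
  if (as.integer(hdr$NDims) != 3L) stop("only 3D MetaImage supported: ", path)
  if (!is.null(hdr$BinaryData) && tolower(hdr$BinaryData) != "true")
    stop("only binary MetaImage supported: ", path)
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage not supported: ", path)
  msb <- !is.null(hdr$BinaryDataByteOrderMSB) && tolower(hdr$BinaryDataByteOrderMSB) == "true"
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- diag(3)
  if (!is.null(hdr$TransformMatrix)) {
    # ITK writes direction cosines row-major, column j = direction of axis j
    m <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    direction <- t(matrix(m, 3, 3))
  }
  n <- prod(d)
  type <- hdr$ElementType
  vox <- switch(type,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = if (msb) "big" else "little"),
    MET_FLOAT  = readBin(con, "double", n = n, size = 4, endian = if (msb) "big" else "little"),
    MET_SHORT  = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                         endian = if (msb) "big" else "little"),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = if (msb) "big" else "little"),
    MET_UCHAR  = as.integer(readBin(con, "raw", n = n)),
    stop("unsupported MetaImage ElementType '", type, "' in ", path))
  if (!identical(data_file, "LOCAL")) {
    # .mhd with raw sidecar: reopen the payload from the referenced file
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    con2 <- file(raw_path, "rb")
    on.exit(close(con2), add = TRUE)
    vox <- switch(type,
      MET_DOUBLE = readBin(con2, "double", n = n, size = 8, endian = if (msb) "big" else "little"),
      MET_FLOAT  = readBin(con2, "double", n = n, size = 4, endian = if (msb) "big" else "little"),
      MET_SHORT  = readBin(con2, "integer", n = n, size = 2, signed = TRUE,
                           endian = if (msb) "big" else "little"),
      MET_USHORT = readBin(con2, "integer", n = n, size = 2, signed = FALSE,
                           endian = if (msb) "big" else "little"),
      MET_UCHAR  = as.integer(readBin(con2, "raw", n = n)))
  }
  if (length(vox) != n) stop("truncated MetaImage voxel data in ", path)
  image3d(array(as.numeric(vox), d), origin = origin, spacing = spacing,
          direction = direction)
}

write_metaimage <- function(img, path) {
  d <- dim(img$voxels)
  mhd <- grepl("\\.mhd$", tolower(path))
  data_file <- if (mhd) paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
               else "LOCAL"
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(as.vector(t(img$direction)), digits = 17),
                                     collapse = " ")),
    paste("Offset =", paste(format(img$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(img$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", data_file))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (mhd) {
    con2 <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(con2), add = TRUE)
    writeBin(as.numeric(img$voxels), con2, size = 8, endian = "little")
  } else {
    writeBin(as.numeric(img$voxels), con, size = 8, endian = "little")
  }
  invisible(NULL)
}
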
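#' Named landmark sets in world coordinates
#'
#' A set of N >= 1 uniquely named 3D points in world mm (LPS). Landmark files
#' are CSV with header `name,x,y,z`; order is preserved and correspondence
#' between a target set and a source set is by row order.
#'
#' @param names character vector of unique labels.
#' @param points N x 3 numeric matrix of world coordinates (mm).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(names, points) {
  points <- to_points_matrix(points)
  names <- as.character(names)
  if (nrow(points) < 1L) stop("a landmark set needs at least one point")
  if (length(names) != nrow(points)) stop("one name per point required")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  structure(list(names = names, points = points), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set with", nrow(x$points), "points\n")
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$points)

#' Read and write landmark CSV files
#'
#' @param path CSV file with header `name,x,y,z`, coordinates in world mm.
#' @return [read_landmarks()] returns a [landmark_set];
#'   [write_landmarks()] is called for its side effect.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty landmark file: ", path)
  header <- tolower(gsub("\\s", "", lines[1]))
  if (header != "name,x,y,z")
    stop("landmark file must start with header 'name,x,y,z': ", path)
  if (length(lines) < 2L) stop("landmark file has no data rows: ", path)
  nm <- character(0); pts <- NULL
  rows <- vector("list", length(lines) - 1L)
  for (i in seq.int(2L, length(lines))) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      stop("line ", i, ": expected 4 comma-separated fields")
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz)))
      stop("line ", i, ": non-numeric coordinate in landmark file")
    nm <- c(nm, trimws(f[1]))
    rows[[i - 1L]] <- xyz
  }
  if (anyDuplicated(nm)) {
    dup <- which(duplicated(nm))[1] + 1L
    stop("line ", dup, ": duplicate landmark name '", nm[duplicated(nm)][1], "'")
  }
  landmark_set(nm, do.call(rbind, rows))
}

#' @rdname read_landmarks
#' @param ls a [landmark_set].
#' @export
write_landmarks <- function(ls, path) {
  stopifnot(inherits(ls, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("name,x,y,z", con)
  for (i in seq_len(nrow(ls$points)))
    writeLines(paste(ls$names[i],
                     format(ls$points[i, 1], digits = 17),
                     format(ls$points[i, 2], digits = 17),
                     format(ls$points[i, 3], digits = 17), sep = ","), con)
  invisible(NULL)
}
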
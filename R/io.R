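# Delimited-text spectrum tables and the binary map container.
#
# Two text dialects are supported for interchange:
#   long: rows of (wavenumber, intensity) for a single spectrum, or
#         (wavenumber, intensity, x, y) for a map;
#   wide: a header row of wavenumbers, then one intensity row per pixel.
# The binary container is the package's native single-file map format:
# a magic tag, a format version, typed datasets (axis, cube, mask) and a
# serialized metadata block, so a round trip is lossless.

CONTAINER_MAGIC <- charToRaw("RAMANMAP")
CONTAINER_VERSION <- 1L

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("'%s' is empty", path))
  if (grepl("\t", first)) "\t" else ","
}

check_ragged <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged table '%s': line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  nf[1L]
}

#' Read a spectrum or map from a delimited text table
#'
#' @param path Path to a CSV or TSV file (separator auto-detected unless
#'   given).
#' @param dialect `"long"` for (wavenumber, intensity\[, x, y\]) rows;
#'   `"wide"` for a header row of wavenumbers followed by one row per pixel.
#' @param sep Field separator; `NULL` (default) auto-detects `,` vs tab.
#' @param nx,ny Optional map shape for the wide dialect; defaults to one
#'   row of pixels (`nx` = number of data rows, `ny = 1`).
#' @return A [raman_spectrum] (long dialect, 2 columns) or [raman_map].
#' @export
read_spectrum_table <- function(path, dialect = c("long", "wide"), sep = NULL,
                                nx = NULL, ny = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  if (is.null(sep)) sep <- detect_sep(path)
  check_ragged(path, sep)

  if (dialect == "long") {
    df <- utils::read.table(path, sep = sep, header = looks_like_header(path, sep),
                            stringsAsFactors = FALSE)
    if (ncol(df) == 2L) {
      ord <- order(df[[1L]])
      return(raman_spectrum(df[[1L]][ord], df[[2L]][ord],
                            meta = list(source = path)))
    }
    if (ncol(df) == 4L) {
      names(df) <- c("wavenumber", "intensity", "x", "y")
      axis <- sort(unique(df$wavenumber))
      xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
      nx <- length(xs); ny <- length(ys)
      cube <- matrix(NA_real_, nx * ny, length(axis))
      ix <- match(df$x, xs); iy <- match(df$y, ys)
      p <- (iy - 1L) * nx + ix
      j <- match(df$wavenumber, axis)
      cube[cbind(p, j)] <- df$intensity
      if (anyNA(cube))
        stop("long map table does not cover every (pixel, wavenumber) pair")
      return(raman_map(axis, cube, nx, ny, meta = list(source = path)))
    }
    stop(sprintf("long dialect expects 2 or 4 columns, found %d", ncol(df)))
  }

  # wide: header row of wavenumbers, then one row per pixel
  header <- scan(path, what = character(), sep = sep, nlines = 1L, quiet = TRUE)
  wn <- suppressWarnings(as.numeric(header))
  if (anyNA(wn)) stop("wide dialect requires a numeric wavenumber header row")
  dup <- which(duplicated(wn))
  if (length(dup))
    stop(sprintf("duplicated wavenumber column: %.6g cm^-1", wn[dup[1L]]))
  body <- utils::read.table(path, sep = sep, skip = 1L)
  if (ncol(body) != length(wn))
    stop(sprintf("wide table has %d header fields but %d data columns",
                 length(wn), ncol(body)))
  ord <- order(wn)
  cube <- as.matrix(body)[, ord, drop = FALSE]
  dimnames(cube) <- NULL
  npix <- nrow(cube)
  if (is.null(nx)) { nx <- npix; ny <- 1L }
  raman_map(wn[ord], cube, nx, ny, meta = list(source = path))
}

looks_like_header <- function(path, sep) {
  first <- scan(path, what = character(), sep = sep, nlines = 1L, quiet = TRUE)
  anyNA(suppressWarnings(as.numeric(first)))
}

#' Write a spectrum or map as a delimited text table
#'
#' @param x A [raman_spectrum] or [raman_map].
#' @param path Output path.
#' @param dialect `"long"` or `"wide"` (see [read_spectrum_table]).
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(x, path, dialect = c("long", "wide"), sep = ",") {
  dialect <- match.arg(dialect)
  if (inherits(x, "raman_spectrum")) {
    if (dialect != "long") stop("a single spectrum is written in the long dialect")
    utils::write.table(data.frame(wavenumber = x$wavenumber, intensity = x$intensity),
                       path, sep = sep, row.names = FALSE, col.names = TRUE,
                       quote = FALSE)
    return(invisible(path))
  }
  if (!inherits(x, "raman_map")) stop("expected a raman_spectrum or raman_map")
  if (dialect == "wide") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(format(x$wavenumber, digits = 17, trim = TRUE), collapse = sep), con)
    utils::write.table(x$cube, con, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    px <- rep(seq_len(x$nx), times = x$ny)
    py <- rep(seq_len(x$ny), each = x$nx)
    df <- data.frame(
      wavenumber = rep(x$wavenumber, each = nrow(x$cube)),
      intensity = as.vector(x$cube),
      x = rep(px, times = length(x$wavenumber)),
      y = rep(py, times = length(x$wavenumber)))
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' Write a map to the binary container format
#'
#' Single-file layout: magic tag, format version, shape, pixel spacing,
#' axis, cube, mask, and a serialized metadata block. The round trip
#' through [read_map_container()] is lossless.
#'
#' @param map A [raman_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_container <- function(map, path) {
  stopifnot(inherits(map, "raman_map"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(CONTAINER_MAGIC, con)
  writeBin(CONTAINER_VERSION, con, size = 4L)
  writeBin(c(map$nx, map$ny, length(map$wavenumber)), con, size = 4L)
  writeBin(map$spacing_um, con, size = 8L)
  writeBin(map$wavenumber, con, size = 8L)
  writeBin(as.vector(map$cube), con, size = 8L)
  writeBin(as.integer(map$mask), con, size = 4L)
  meta_raw <- serialize(map$meta, NULL, ascii = FALSE)
  writeBin(length(meta_raw), con, size = 4L)
  writeBin(meta_raw, con)
  invisible(path)
}

#' Read a map from the binary container format
#'
#' @param path Path written by [write_map_container()].
#' @return A [raman_map].
#' @export
read_map_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = length(CONTAINER_MAGIC))
  if (!identical(magic, CONTAINER_MAGIC))
    stop(sprintf("'%s' is not a map container (bad magic)", path))
  version <- readBin(con, "integer", n = 1L, size = 4L)
  if (!identical(version, CONTAINER_VERSION))
    stop(sprintf("container version %d not supported (expected %d)",
                 version, CONTAINER_VERSION))
  shp <- readBin(con, "integer", n = 3L, size = 4L)
  if (length(shp) < 3L) stop(sprintf("truncated container: '%s'", path))
  nx <- shp[1L]; ny <- shp[2L]; L <- shp[3L]
  spacing <- readBin(con, "double", n = 1L, size = 8L)
  axis <- readBin(con, "double", n = L, size = 8L)
  cube <- readBin(con, "double", n = nx * ny * L, size = 8L)
  mask <- readBin(con, "integer", n = nx * ny, size = 4L)
  if (length(axis) < L || length(cube) < nx * ny * L || length(mask) < nx * ny)
    stop(sprintf("truncated container: '%s'", path))
  meta_len <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(meta_len) < 1L) stop(sprintf("truncated container: '%s'", path))
  meta_raw <- readBin(con, "raw", n = meta_len)
  if (length(meta_raw) < meta_len) stop(sprintf("truncated container: '%s'", path))
  meta <- unserialize(meta_raw)
  raman_map(axis, matrix(cube, nx * ny, L), nx, ny, spacing_um = spacing,
            mask = as.logical(mask), meta = meta)
}

#' Resample a spectrum or reference set onto a target axis
#'
#' Linear interpolation onto the target wavenumber axis. Target bands
#' outside the source span are filled with the nearest edge value and
#' reported in the returned object's metadata (`extrapolated`).
#'
#' @param x A [raman_spectrum] or [reference_set].
#' @param axis Target wavenumber axis.
#' @return Object of the same class on the target axis.
#' @export
resample_to_axis <- function(x, axis) {
  axis <- wavenumber_axis(axis, range = NULL)
  src <- spectra_axis(x)
  if (axis[length(axis)] < src[1L] || axis[1L] > src[length(src)])
    stop("target axis does not overlap the source axis")
  out_of_range <- axis < src[1L] | axis > src[length(src)]
  interp <- function(y) stats::approx(src, y, xout = axis, rule = 2)$y
  if (inherits(x, "raman_spectrum")) {
    out <- raman_spectrum(axis, interp(x$intensity), label = x$label, meta = x$meta)
    out$meta$extrapolated <- which(out_of_range)
    return(out)
  }
  if (inherits(x, "reference_set")) {
    spec <- t(apply(x$spectra, 1L, interp))
    out <- reference_set(axis, spec, x$names, meta = x$meta)
    out$meta$extrapolated <- which(out_of_range)
    return(out)
  }
  stop("resample_to_axis expects a raman_spectrum or reference_set")
}
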
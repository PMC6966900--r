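#' Validate a wavenumber axis
#'
#' A wavenumber axis is a strictly increasing numeric vector of Raman shifts
#' in cm^-1, lying inside a declared spectral range (by default the
#' 580--3062 cm^-1 window of a typical confocal Raman acquisition of plant
#' tissue).
#'
#' @param values Numeric vector of Raman shifts (cm^-1).
#' @param range Length-2 numeric; permitted closed interval for the axis.
#' @return The validated numeric axis (invisibly the same vector).
#' @export
wavenumber_axis <- function(values, range = c(580, 3062)) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values)))
    stop("wavenumber axis must be finite and non-empty")
  d <- diff(values)
  if (length(d) && any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    if (values[bad + 1L] == values[bad])
      stop(sprintf("wavenumber axis has a duplicated value at %.6g cm^-1 (positions %d, %d)",
                   values[bad], bad, bad + 1L))
    stop(sprintf("wavenumber axis is not strictly increasing at position %d (%.6g -> %.6g cm^-1)",
                 bad, values[bad], values[bad + 1L]))
  }
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (values[1L] < range[1L] || values[length(values)] > range[2L])
      stop(sprintf("axis [%.6g, %.6g] lies outside the declared range [%.6g, %.6g] cm^-1",
                   values[1L], values[length(values)], range[1L], range[2L]))
  }
  values
}

#' Default synthetic wavenumber axis
#'
#' 1015 bands spanning 580--3062 cm^-1 (about 2.45 cm^-1 per band), the
#' sampling used throughout the synthetic-data module.
#'
#' @return Numeric axis of length 1015.
#' @export
default_axis <- function() {
  seq(580, 3062, length.out = 1015L)
}

#' Index of the axis band nearest a wavenumber
#'
#' Bands are always named by wavenumber, never by index; this maps a
#' wavenumber to the nearest axis point, breaking ties toward the lower
#' wavenumber.
#'
#' @param axis Numeric wavenumber axis.
#' @param wavenumber Scalar wavenumber (cm^-1); must lie inside the axis span.
#' @return Integer index into `axis`.
#' @export
band_index <- function(axis, wavenumber) {
  stopifnot(length(wavenumber) == 1L, is.finite(wavenumber))
  if (wavenumber < axis[1L] || wavenumber > axis[length(axis)])
    stop(sprintf("wavenumber %.6g cm^-1 is outside the axis span [%.6g, %.6g]",
                 wavenumber, axis[1L], axis[length(axis)]))
  d <- abs(axis - wavenumber)
  m <- min(d)
  # ties to the lower wavenumber
  which(d <= m + 1e-12)[1L]
}

#' Construct a single Raman spectrum
#'
#' @param wavenumber Strictly increasing axis (cm^-1).
#' @param intensity Numeric intensities (arbitrary counts), one per band.
#' @param label Optional class tag (e.g. "untreated", "treated").
#' @param meta Free-form provenance list.
#' @return Object of class `raman_spectrum` with fields `wavenumber`,
#'   `intensity`, `label`, `meta`.
#' @export
raman_spectrum <- function(wavenumber, intensity, label = NULL, meta = list()) {
  wavenumber <- wavenumber_axis(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavenumber))
    stop(sprintf("intensity length (%d) does not match axis length (%d)",
                 length(intensity), length(wavenumber)))
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must be finite")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 label = label, meta = meta),
            class = "raman_spectrum")
}

#' Construct a hyperspectral Raman map
#'
#' A map scan holds one spectrum per spatial pixel on an `nx` x `ny` grid.
#' Pixels are stored row-major with origin at the top-left: pixel
#' `p = (iy - 1) * nx + ix`, with `ix` the column (x) and `iy` the row (y).
#' The cube is the spatially unfolded spectrum matrix (one row per pixel).
#'
#' @param wavenumber Strictly increasing axis (cm^-1), length L.
#' @param cube Numeric matrix, `(nx*ny) x L`, one spectrum per row.
#' @param nx,ny Pixel counts along x (columns) and y (rows).
#' @param spacing_um Pixel spacing in micrometres (default 2.5).
#' @param mask Logical foreground flag per pixel (default all TRUE).
#' @param meta Free-form provenance list.
#' @return Object of class `raman_map`.
#' @export
raman_map <- function(wavenumber, cube, nx, ny, spacing_um = 2.5,
                      mask = NULL, meta = list()) {
  wavenumber <- wavenumber_axis(wavenumber)
  cube <- as.matrix(cube)
  storage.mode(cube) <- "double"
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("map shape must be at least 1 x 1")
  if (nrow(cube) != nx * ny)
    stop(sprintf("cube has %d rows but nx*ny = %d", nrow(cube), nx * ny))
  if (ncol(cube) != length(wavenumber))
    stop(sprintf("cube has %d bands but axis has %d", ncol(cube), length(wavenumber)))
  if (is.null(mask)) mask <- rep(TRUE, nx * ny)
  mask <- as.logical(mask)
  if (length(mask) != nx * ny)
    stop(sprintf("mask length (%d) does not match pixel count (%d)", length(mask), nx * ny))
  structure(list(wavenumber = wavenumber, cube = cube, nx = nx, ny = ny,
                 spacing_um = as.numeric(spacing_um), mask = mask, meta = meta),
            class = "raman_map")
}

#' Construct a set of pure-component reference spectra
#'
#' The reference set is the matrix of k pure component spectra (one row per
#' component) against which map pixels are unmixed. Its axis must be
#' identical to the map's; use [resample_to_axis()] first if it is not.
#'
#' @param wavenumber Strictly increasing axis (cm^-1), length L.
#' @param spectra Numeric `k x L` matrix of component spectra.
#' @param names Character component identifiers of length k.
#' @param meta Free-form provenance list.
#' @return Object of class `reference_set`.
#' @export
reference_set <- function(wavenumber, spectra, names, meta = list()) {
  wavenumber <- wavenumber_axis(wavenumber)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (nrow(spectra) < 1L) stop("reference set needs at least one component")
  if (ncol(spectra) != length(wavenumber))
    stop(sprintf("reference spectra have %d bands but axis has %d",
                 ncol(spectra), length(wavenumber)))
  names <- as.character(names)
  if (length(names) != nrow(spectra))
    stop("one name per component spectrum is required")
  rownames(spectra) <- names
  structure(list(wavenumber = wavenumber, spectra = spectra,
                 names = names, meta = meta),
            class = "reference_set")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d bands, %.5g-%.5g cm^-1%s\n",
              length(x$wavenumber), x$wavenumber[1L],
              x$wavenumber[length(x$wavenumber)],
              if (!is.null(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf("<raman_map> %d x %d pixels (%.3g um spacing), %d bands, %d/%d foreground\n",
              x$nx, x$ny, x$spacing_um, length(x$wavenumber),
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d components (%s), %d bands\n",
              nrow(x$spectra), paste(x$names, collapse = ", "),
              length(x$wavenumber)))
  invisible(x)
}

# intensity matrix view of spectrum collections used by several modules:
# a list of raman_spectrum, a raman_map, or a bare matrix
spectra_matrix <- function(x) {
  if (inherits(x, "raman_map")) return(x$cube)
  if (inherits(x, "raman_spectrum")) return(matrix(x$intensity, nrow = 1L))
  if (is.list(x) && length(x) && inherits(x[[1L]], "raman_spectrum")) {
    L <- length(x[[1L]]$intensity)
    ok <- vapply(x, function(s) length(s$intensity) == L, logical(1L))
    if (!all(ok)) stop("spectra in the set have differing band counts")
    return(do.call(rbind, lapply(x, function(s) s$intensity)))
  }
  if (is.matrix(x)) return(x)
  stop("expected a raman_map, raman_spectrum, list of spectra, or matrix")
}

spectra_axis <- function(x) {
  if (inherits(x, "raman_map") || inherits(x, "raman_spectrum") ||
      inherits(x, "reference_set")) return(x$wavenumber)
  if (is.list(x) && length(x) && inherits(x[[1L]], "raman_spectrum"))
    return(x[[1L]]$wavenumber)
  stop("object carries no wavenumber axis")
}

spectra_labels <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1L]], "raman_spectrum"))
    return(vapply(x, function(s) s$label %||% NA_character_, character(1L)))
  stop("labels are only defined for a list of spectra")
}
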
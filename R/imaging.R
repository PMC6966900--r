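# Chemical images, single-band images, concentration histograms and the
# composition arithmetic that ties microscopic images back to bulk
# wet-chemistry measurements.

chemical_image <- function(component, grid, units, meta = list()) {
  structure(list(component = component, grid = grid, units = units,
                 meta = meta),
            class = "chemical_image")
}

#' @export
print.chemical_image <- function(x, ...) {
  cat(sprintf("<chemical_image> %s, %d x %d, units: %s\n",
              x$component, ncol(x$grid), nrow(x$grid), x$units))
  invisible(x)
}

#' @export
plot.chemical_image <- function(x, ...) {
  g <- x$grid[rev(seq_len(nrow(x$grid))), , drop = FALSE]
  graphics::image(t(g), main = sprintf("%s (%s)", x$component, x$units),
                  axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}

# abundance/calibrated column -> ny x nx grid (row-major pixel order)
result_grid <- function(result, values) {
  v <- values
  v[!result$mask] <- NA_real_
  matrix(v, result$ny, result$nx, byrow = TRUE)
}

#' Chemical images from an unmixing result
#'
#' One image per component; calibrated concentrations (percent dry base)
#' when [calibrate()] has run, abundance fractions otherwise. Masked
#' pixels are absent (`NA`).
#'
#' @param result An [unmix_map()] result.
#' @param calibrated Use calibrated concentrations if available.
#' @return Named list of `chemical_image`.
#' @export
chemical_images <- function(result, calibrated = TRUE) {
  stopifnot(inherits(result, "abundance_result"))
  use_cal <- calibrated && !is.null(result$calibrated)
  vals <- if (use_cal) result$calibrated else result$abundance
  units <- if (use_cal) "% d.b." else "fraction"
  out <- lapply(result$references, function(cmp)
    chemical_image(cmp, result_grid(result, vals[, cmp]), units,
                   meta = list(references = result$references, W = result$W,
                               normalize = result$normalize)))
  stats::setNames(out, result$references)
}

#' Single-band intensity image
#'
#' Per-pixel raw intensity at the axis point nearest the requested
#' wavenumber: the traditional one-band imaging method, retained for
#' comparison against unmixing-based chemical images. Masked pixels are
#' absent.
#'
#' @param map A [raman_map].
#' @param wavenumber Band, cm^-1 (inside the axis).
#' @return A `chemical_image` whose grid holds intensities
#'   (arbitrary units).
#' @export
single_band_image <- function(map, wavenumber) {
  stopifnot(inherits(map, "raman_map"))
  j <- band_index(map$wavenumber, wavenumber)
  v <- map$cube[, j]
  v[!map$mask] <- NA_real_
  chemical_image(sprintf("%.5g cm^-1", map$wavenumber[j]),
                 matrix(v, map$ny, map$nx, byrow = TRUE), "a.u.",
                 meta = list(wavenumber = map$wavenumber[j]))
}

#' Per-component concentration histogram table
#'
#' Bins the foreground pixel values of each chemical image on a common
#' set of breaks. Total counts per component equal the number of
#' foreground pixels.
#'
#' @param images A `chemical_image` or list of them.
#' @param bins Number of bins (>= 1) or an explicit breaks vector.
#' @return Data frame with columns `component`, `bin_lo`, `bin_hi`,
#'   `count`.
#' @export
concentration_histogram <- function(images, bins = 30L) {
  if (inherits(images, "chemical_image")) images <- list(images)
  stopifnot(length(images) >= 1L,
            all(vapply(images, inherits, logical(1L), "chemical_image")))
  vals <- lapply(images, function(im) im$grid[!is.na(im$grid)])
  if (!any(lengths(vals) > 0)) stop("no foreground pixels to histogram")
  if (length(bins) == 1L) {
    bins <- as.integer(bins)
    if (bins < 1L) stop("at least one bin is required")
    rng <- range(unlist(vals))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  } else {
    breaks <- as.numeric(bins)
    if (length(breaks) < 2L) stop("breaks must define at least one bin")
  }
  out <- list()
  for (i in seq_along(images)) {
    h <- graphics::hist(vals[[i]], breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    out[[i]] <- data.frame(component = images[[i]]$component,
                           bin_lo = h$breaks[-length(h$breaks)],
                           bin_hi = h$breaks[-1L], count = h$counts,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Relative composition change between two measured states
#'
#' For each named component computes the relative reduction
#' `(before - after) / before * 100`, reported both raw and rounded to
#' the nearest integer percent, plus the combined totals (CHL) of both
#' states. Optionally appends the relative gas-yield change
#' `(after - before) / before * 100` to one decimal. When `printed`
#' reductions (integer percent) are supplied, rounded values that
#' disagree are flagged rather than silently replaced.
#'
#' @param before,after Named numeric vectors of component contents
#'   (percent dry base, > 0), same names.
#' @param gas Optional length-2 numeric `(yield_before, yield_after)`.
#' @param printed Optional named integer percent reductions to
#'   cross-check against.
#' @return Object of class `composition_report`: data frame `components`
#'   (with `before`, `after`, `reduction_raw`, `reduction_pct`, and
#'   `matches_printed` when `printed` given), `chl_before`, `chl_after`,
#'   `chl_delta`, and `gas_change_pct` when `gas` given.
#' @export
composition_report <- function(before, after, gas = NULL, printed = NULL) {
  if (is.null(names(before)) || is.null(names(after)))
    stop("before and after must be named by component")
  missing <- setdiff(names(before), names(after))
  if (length(missing))
    stop(sprintf("component '%s' missing from 'after'", missing[1L]))
  after <- after[names(before)]
  if (any(before <= 0) || any(after <= 0))
    stop("component contents must be positive")
  raw <- (before - after) / before * 100
  comp <- data.frame(component = names(before), before = as.numeric(before),
                     after = as.numeric(after),
                     reduction_raw = as.numeric(raw),
                     reduction_pct = as.numeric(round(raw)),
                     stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(printed)) {
    comp$printed <- as.numeric(printed[comp$component])
    comp$matches_printed <- comp$reduction_pct == comp$printed
  }
  out <- list(components = comp,
              chl_before = sum(before), chl_after = sum(after),
              chl_delta = sum(before) - sum(after))
  if (!is.null(gas)) {
    stopifnot(length(gas) == 2L, all(gas > 0))
    out$gas_before <- gas[1L]; out$gas_after <- gas[2L]
    out$gas_change_pct <- round((gas[2L] - gas[1L]) / gas[1L] * 100, 1)
  }
  structure(out, class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("<composition_report>\n")
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-14s %6.2f -> %6.2f  (reduced %.1f%%, ~%d%%%s)\n",
                comp$component[i], comp$before[i], comp$after[i],
                comp$reduction_raw[i], comp$reduction_pct[i],
                if (!is.null(comp$matches_printed) && !comp$matches_printed[i])
                  sprintf("; printed value %g disagrees", comp$printed[i]) else ""))
  }
  cat(sprintf("  totals: %.4g -> %.4g (delta %.4g)\n",
              x$chl_before, x$chl_after, x$chl_delta))
  if (!is.null(x$gas_change_pct))
    cat(sprintf("  gas yield: %.4g -> %.4g (%+.1f%%)\n",
                x$gas_before, x$gas_after, x$gas_change_pct))
  invisible(x)
}
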
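# Synthetic lignocellulose scenes with known ground truth.
#
# Real plant-tissue map scans are rarely shareable, so validation runs on
# synthetic scenes built from the same linear mixing model the unmixing
# inverts: cube = abundance %*% references + nuisance. The nuisance terms
# emulate what confocal Raman maps of resin-embedded tissue actually show:
# a smooth fluorescence background that grows with wavenumber, Gaussian
# shot-like noise, and isolated cosmic-ray spikes.

#' Describe one pure-component spectral model
#'
#' @param name Component name.
#' @param peaks Data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sd, cm^-1) and `height` (relative, >= 0).
#' @param fluor_amp Amplitude of the smooth fluorescence baseline (same
#'   units as peak heights).
#' @param fluor_curv Curvature exponent of the baseline; the baseline is
#'   `fluor_amp * u^fluor_curv` with `u` the axis position rescaled to
#'   \[0, 1\], so it increases with wavenumber.
#' @return Object of class `component_model`.
#' @export
component_model <- function(name, peaks, fluor_amp = 0, fluor_curv = 2) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "width", "height") %in% names(peaks)),
            all(peaks$width > 0), all(peaks$height >= 0), fluor_amp >= 0)
  structure(list(name = name, peaks = peaks,
                 fluor_amp = fluor_amp, fluor_curv = fluor_curv),
            class = "component_model")
}

#' Evaluate a component model on an axis
#'
#' @param model A [component_model].
#' @param axis Wavenumber axis.
#' @param include_fluorescence Include the smooth baseline term? Set
#'   `FALSE` to obtain the peak-only "truth" signal used when checking
#'   fluorescence suppression.
#' @return Numeric intensity vector.
#' @export
component_spectrum <- function(model, axis, include_fluorescence = TRUE) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(model$peaks))) {
    p <- model$peaks[i, ]
    y <- y + p$height * exp(-0.5 * ((axis - p$center) / p$width)^2)
  }
  if (include_fluorescence && model$fluor_amp > 0) {
    u <- (axis - axis[1L]) / (axis[length(axis)] - axis[1L])
    y <- y + model$fluor_amp * u^model$fluor_curv
  }
  y
}

#' Default lignocellulosic component models and reference set
#'
#' Three components mimicking Raman spectra of lignocellulosic standards:
#' * cellulose: sharp skeletal/C-O peaks (including 1089 cm^-1) with
#'   negligible fluorescence;
#' * lignin: aromatic-ring peaks at 1508 and 1620 cm^-1 over a moderate
#'   fluorescence background;
#' * hemicellulose (xylan-like): weak 1089 and 1739 cm^-1 features buried
#'   under a strong fluorescence background, so the reference shows no
#'   obvious peaks.
#'
#' Reference spectra are the model spectra with their fluorescence term
#' included (as measured standards would be) and are max-normalized to
#' \[0, 1\] per row.
#'
#' @param axis Wavenumber axis (default [default_axis()]).
#' @return List with elements `references` (a [reference_set]) and
#'   `models` (named list of [component_model]).
#' @export
default_components <- function(axis = default_axis()) {
  models <- list(
    cellulose = component_model(
      "cellulose",
      data.frame(center = c(898, 1089, 1121, 1340, 1380, 2895),
                 width  = c(9, 8, 8, 11, 10, 18),
                 height = c(0.45, 1.00, 0.72, 0.30, 0.48, 0.80)),
      fluor_amp = 0.05, fluor_curv = 2),
    hemicellulose = component_model(
      "hemicellulose",
      data.frame(center = c(1089, 1460, 1739, 2930),
                 width  = c(10, 12, 12, 20),
                 height = c(0.12, 0.08, 0.18, 0.10)),
      fluor_amp = 2.0, fluor_curv = 1.8),
    lignin = component_model(
      "lignin",
      data.frame(center = c(1140, 1331, 1508, 1620, 1660, 2940),
                 width  = c(10, 12, 10, 10, 12, 20),
                 height = c(0.25, 0.35, 0.55, 1.00, 0.40, 0.35)),
      fluor_amp = 0.8, fluor_curv = 2)
  )
  spectra <- t(vapply(models, component_spectrum, numeric(length(axis)),
                      axis = axis))
  spectra <- spectra / apply(spectra, 1L, max)
  list(references = reference_set(axis, spectra, names(models),
                                  meta = list(origin = "synthetic standards")),
       models = models)
}

#' Nuisance-signal settings for scene rendering
#'
#' @param gaussian_sd Additive Gaussian noise sd, in units of the
#'   max-normalized references (0.02 = 2% of the strongest peak).
#' @param spike_rate Expected number of cosmic-ray spikes per spectrum
#'   (Poisson-placed).
#' @param spike_mag Length-2 range of spike magnitude as a multiple of the
#'   local signal.
#' @param baseline_scale Amplitude of the per-pixel nuisance fluorescence
#'   background; each pixel's amplitude is jittered by +/- 20%.
#' @param baseline_curv Curvature exponent of the nuisance background
#'   shape `u^baseline_curv` (u = axis position rescaled to \[0, 1\]);
#'   2 gives a quadratic rise concentrated at high wavenumbers, values
#'   below 1 spread the background across the fingerprint region.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 0.02, spike_rate = 0.05,
                       spike_mag = c(5, 20), baseline_scale = 1.0,
                       baseline_curv = 2) {
  if (gaussian_sd < 0) stop("gaussian noise sd must be non-negative")
  if (spike_rate < 0 || baseline_scale < 0)
    stop("spike rate and baseline scale must be non-negative")
  if (baseline_curv <= 0) stop("baseline curvature must be positive")
  structure(list(gaussian_sd = gaussian_sd, spike_rate = spike_rate,
                 spike_mag = as.numeric(spike_mag),
                 baseline_scale = baseline_scale,
                 baseline_curv = baseline_curv),
            class = "noise_spec")
}

# smooth wavenumber-increasing fluorescence shape shared by nuisance terms
fluor_shape <- function(axis, curv = 2) {
  u <- (axis - axis[1L]) / (axis[length(axis)] - axis[1L])
  u^curv
}

# draw one Dirichlet row proportional to alpha
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha
  g / sum(g)
}

RESIN_LEVEL <- 0.02

# cell-type layouts; returns list(labels chr[npix], abundance npix x k)
scene_layout <- function(layout, nx, ny, k, jitter_conc = 150) {
  labels <- matrix("parenchyma", ny, nx)
  # mixtures are (cellulose, hemicellulose, lignin) proportions
  base <- list(
    background    = c(0, 0, 0),
    epidermis     = c(0.30, 0.12, 0.58),
    parenchyma    = c(0.50, 0.38, 0.12),
    sclerenchyma  = c(0.42, 0.16, 0.42),
    xylem         = c(0.32, 0.14, 0.54),
    `vascular bundle` = c(0.42, 0.30, 0.28))
  if (layout == "tiles") {
    # k component tiles plus one background tile, as vertical strips
    cuts <- round(seq(0, nx, length.out = k + 2L))
    tile_names <- c("cellulose tile", "hemicellulose tile", "lignin tile")[seq_len(k)]
    labels[] <- "background"
    ab <- matrix(0, nx * ny, k)
    for (t in seq_len(k)) {
      cols <- (cuts[t] + 1L):cuts[t + 1L]
      labels[, cols] <- tile_names[t]
      for (ix in cols) ab[(seq_len(ny) - 1L) * nx + ix, t] <- 1
    }
    return(list(labels = as.vector(t(labels)), abundance = ab))
  }
  if (layout == "random-simplex") {
    ab <- t(replicate(nx * ny, rdirichlet1(rep(1, k))))
    return(list(labels = rep("parenchyma", nx * ny), abundance = ab))
  }
  # "cells": background frame, epidermis strips, sclerenchyma/xylem patches,
  # vascular bundles around the xylem, parenchyma elsewhere
  border <- max(1L, round(min(nx, ny) * 0.06))
  labels[c(seq_len(border), ny - seq_len(border) + 1L), ] <- "background"
  labels[, c(seq_len(border), nx - seq_len(border) + 1L)] <- "background"
  epi <- border + seq_len(max(1L, round(ny * 0.08)))
  labels[epi, (border + 1L):(nx - border)] <- "epidermis"
  labels[ny - epi + 1L, (border + 1L):(nx - border)] <- "epidermis"
  # two vascular bundles with xylem cores, plus a sclerenchyma band
  centres <- rbind(c(0.35, 0.5), c(0.7, 0.5))
  rad_vb <- 0.12 * min(nx, ny); rad_xy <- 0.05 * min(nx, ny)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (labels[iy, ix] %in% c("background", "epidermis")) next
    for (ctr in seq_len(nrow(centres))) {
      dx <- ix - centres[ctr, 1L] * nx; dy <- iy - centres[ctr, 2L] * ny
      r <- sqrt(dx^2 + dy^2)
      if (r <= rad_xy) labels[iy, ix] <- "xylem"
      else if (r <= rad_vb && labels[iy, ix] == "parenchyma")
        labels[iy, ix] <- "vascular bundle"
    }
  }
  scl <- (border + max(epi) + 1L):(border + max(epi) + max(1L, round(ny * 0.06)))
  scl <- scl[scl <= ny - border]
  labels[scl, (border + 1L):(nx - border)][labels[scl, (border + 1L):(nx - border)] == "parenchyma"] <- "sclerenchyma"
  lab_vec <- as.vector(t(labels))           # row-major pixel order
  ab <- matrix(0, nx * ny, k)
  for (p in seq_len(nx * ny)) {
    b <- base[[lab_vec[p]]]
    if (sum(b) > 0) ab[p, ] <- rdirichlet1(b[seq_len(k)] * jitter_conc)
  }
  list(labels = lab_vec, abundance = ab)
}

#' Render a synthetic hyperspectral scene with known ground truth
#'
#' Forward model: `cube = abundance %*% references` plus, per foreground
#' pixel, a smooth fluorescence background increasing with wavenumber
#' (amplitude jittered +/- 20% per pixel), additive Gaussian noise, and
#' Poisson-placed cosmic-ray spikes of width 1-2 bands. Background pixels
#' carry a flat, low resin-like signal. Deterministic for a fixed seed.
#'
#' @param layout `"cells"` (tissue-like cell-type regions), `"tiles"`
#'   (pure-component strips plus a background strip) or
#'   `"random-simplex"` (Dirichlet abundance everywhere).
#' @param shape Length-2 integer `(nx, ny)` pixel counts.
#' @param components Component set from [default_components()].
#' @param noise A [noise_spec()].
#' @param effect Optional per-component retention factors (> 0) applied
#'   to the abundance weights before renormalization, emulating a
#'   treatment that removes components unevenly (e.g. the alkali
#'   retention ratios `c(0.87, 0.47, 0.75)`).
#' @param seed Integer seed; all randomness is local to the call.
#' @return Object of class `synthetic_scene`: list with `map`
#'   ([raman_map]), `truth_abundance` (`(nx*ny) x k`, rows on the simplex
#'   for foreground pixels, zero rows for background), `truth_labels`,
#'   `noise`, `seed`, `components`.
#' @export
render_scene <- function(layout = c("cells", "tiles", "random-simplex"),
                         shape = c(40, 50), components = default_components(),
                         noise = noise_spec(), effect = NULL, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  nx <- as.integer(shape[1L]); ny <- as.integer(shape[2L])
  refs <- components$references
  axis <- refs$wavenumber
  k <- nrow(refs$spectra)
  with_seed(seed, {
    lay <- scene_layout(layout, nx, ny, k)
    fg <- lay$labels != "background"
    if (!is.null(effect)) {
      stopifnot(length(effect) == k, all(effect > 0))
      w <- sweep(lay$abundance[fg, , drop = FALSE], 2L, as.numeric(effect), `*`)
      lay$abundance[fg, ] <- w / rowSums(w)
    }
    cube <- lay$abundance %*% refs$spectra
    cube[!fg, ] <- RESIN_LEVEL
    shape_f <- fluor_shape(axis, noise$baseline_curv)
    if (noise$baseline_scale > 0) {
      amp <- noise$baseline_scale * stats::runif(sum(fg), 0.8, 1.2)
      cube[fg, ] <- cube[fg, ] + outer(amp, shape_f)
    }
    if (noise$gaussian_sd > 0)
      cube <- cube + matrix(stats::rnorm(length(cube), sd = noise$gaussian_sd),
                            nrow(cube))
    if (noise$spike_rate > 0) cube <- add_spikes(cube, noise)
    map <- raman_map(axis, cube, nx, ny,
                     meta = list(origin = "synthetic scene", layout = layout,
                                 seed = seed))
    structure(list(map = map, truth_abundance = lay$abundance,
                   truth_labels = lay$labels, noise = noise, seed = seed,
                   components = components),
              class = "synthetic_scene")
  })
}

# Poisson-placed positive outliers of width 1-2 bands, 5-20x local signal
add_spikes <- function(cube, noise) {
  L <- ncol(cube)
  n_spk <- stats::rpois(nrow(cube), noise$spike_rate)
  for (i in which(n_spk > 0)) {
    for (s in seq_len(n_spk[i])) {
      j <- sample.int(L, 1L)
      w <- sample(1:2, 1L)
      mag <- stats::runif(1L, noise$spike_mag[1L], noise$spike_mag[2L])
      local <- max(abs(cube[i, j]), 0.05)
      jj <- j:min(L, j + w - 1L)
      cube[i, jj] <- cube[i, jj] + mag * local
    }
  }
  cube
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d pixels, %d components, layout seed %s\n",
              x$map$nx, x$map$ny, ncol(x$truth_abundance), format(x$seed)))
  print(x$map)
  invisible(x)
}

#' Generate a labeled spot-scan dataset (untreated vs alkali-treated)
#'
#' Emulates averaged spot spectra from many cell types of untreated and
#' alkali-treated tissue. Untreated composition is drawn around dry-base
#' proportions of cellulose/hemicellulose/lignin = 39.5/33.2/4.5; the
#' treated class multiplies the component weights by per-component
#' retention factors before renormalizing, defaulting to the retention
#' ratios 0.87/0.47/0.75 produced by alkali pretreatment.
#'
#' @param n_untreated,n_treated Class sizes (defaults 235 and 339).
#' @param effect Named per-component scale factors applied to the treated
#'   class weights; `c(1, 1, 1)` makes the classes exchangeable.
#' @param components Component set from [default_components()].
#' @param noise A [noise_spec()].
#' @param jitter_conc Dirichlet concentration controlling biological
#'   spread of per-sample composition.
#' @param seed Integer seed.
#' @return List of labeled [raman_spectrum] objects (labels `"untreated"`
#'   and `"treated"`).
#' @export
make_spot_dataset <- function(n_untreated = 235, n_treated = 339,
                              effect = c(cellulose = 0.87,
                                         hemicellulose = 0.47,
                                         lignin = 0.75),
                              components = default_components(),
                              noise = noise_spec(), jitter_conc = 150,
                              seed = 1) {
  stopifnot(all(effect > 0))
  refs <- components$references
  axis <- refs$wavenumber
  k <- nrow(refs$spectra)
  base <- c(39.5, 33.2, 4.5)[seq_len(k)]
  base <- base / sum(base)
  eff <- if (!is.null(names(effect))) effect[refs$names] else effect
  treated_base <- base * as.numeric(eff)
  treated_base <- treated_base / sum(treated_base)
  shape_f <- fluor_shape(axis, noise$baseline_curv)
  with_seed(seed, {
    gen <- function(b, label, n) {
      lapply(seq_len(n), function(i) {
        w <- rdirichlet1(b * jitter_conc)
        y <- as.vector(w %*% refs$spectra)
        if (noise$baseline_scale > 0)
          y <- y + noise$baseline_scale * stats::runif(1L, 0.8, 1.2) * shape_f
        if (noise$gaussian_sd > 0)
          y <- y + stats::rnorm(length(y), sd = noise$gaussian_sd)
        if (noise$spike_rate > 0)
          y <- as.vector(add_spikes(matrix(y, 1L), noise))
        raman_spectrum(axis, y, label = label,
                       meta = list(weights = w))
      })
    }
    c(gen(base, "untreated", n_untreated),
      gen(treated_base, "treated", n_treated))
  })
}
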
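# Noise-reduction chain for Raman maps and spectrum sets:
# background segmentation -> cosmic-ray despiking -> PCA denoising ->
# airPLS baseline correction -> normalization. Impulsive artifacts are
# treated first; rank reduction runs before baseline estimation so the
# (nonlinear) baseline fit sees noise-free spectra and the fluorescence
# structure stays in the retained score subspace. Every stage is usable
# on its own.

#' Segment map background by thresholding a per-pixel score
#'
#' Each pixel is reduced to a scalar score (mean intensity over a band
#' window, by default the full axis); the score is thresholded to separate
#' tissue (foreground) from the embedding-resin background.
#'
#' @param map A [raman_map] with at least 2 pixels.
#' @param strategy `"otsu"` (between-class-variance threshold),
#'   `"quantile"` (threshold at the `q` quantile of scores) or `"manual"`
#'   (threshold at `tau`).
#' @param tau Manual threshold (required for `strategy = "manual"`).
#' @param q Quantile for `strategy = "quantile"` (default 0.5).
#' @param band_window Optional `c(lo, hi)` wavenumber window for the score.
#' @return Logical foreground mask of length `nx * ny`. If every pixel
#'   falls on one side of the threshold a warning is issued and an
#'   all-foreground mask is returned.
#' @export
segment_background <- function(map, strategy = c("otsu", "quantile", "manual"),
                               tau = NULL, q = 0.5, band_window = NULL) {
  stopifnot(inherits(map, "raman_map"))
  strategy <- match.arg(strategy)
  if (nrow(map$cube) < 2L) stop("segmentation needs at least 2 pixels")
  cols <- seq_along(map$wavenumber)
  if (!is.null(band_window)) {
    cols <- which(map$wavenumber >= band_window[1L] & map$wavenumber <= band_window[2L])
    if (!length(cols)) stop("band window contains no axis points")
  }
  score <- rowMeans(map$cube[, cols, drop = FALSE])
  thr <- switch(strategy,
    otsu = otsu_threshold(score),
    quantile = stats::quantile(score, q, names = FALSE),
    manual = {
      if (is.null(tau)) stop("manual segmentation requires tau")
      tau
    })
  mask <- score > thr
  if (all(mask) || !any(mask)) {
    warning("threshold puts every pixel on one side; returning all-foreground mask")
    return(rep(TRUE, length(score)))
  }
  mask
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Bands whose modified z-score against a running median exceeds `z` are
#' replaced by the local median; all other bands are untouched. The
#' z-score scale is the MAD of the running-median residuals with a floor
#' of 0.1% of the signal range, so smooth noise-free peaks are never
#' flagged.
#'
#' @param s A [raman_spectrum] or numeric vector.
#' @param window Odd window width (bands) for the running median, >= 3.
#' @param z Modified z-score threshold (default 8).
#' @return Despiked object of the same type.
#' @export
despike <- function(s, window = 7L, z = 8) {
  y <- if (inherits(s, "raman_spectrum")) s$intensity else as.numeric(s)
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3")
  if (window %% 2L == 0L) stop("window must be odd")
  if (window >= length(y)) stop("window must be smaller than the spectrum length")
  med <- stats::runmed(y, window, endrule = "median")
  resid <- y - med
  scale <- max(1.4826 * stats::median(abs(resid)),
               0.02 * diff(range(y)), .Machine$double.eps)
  spikes <- resid / scale > z
  y[spikes] <- med[spikes]
  if (inherits(s, "raman_spectrum")) {
    s$intensity <- y
    s$meta$despiked_bands <- which(spikes)
    return(s)
  }
  y
}

# despike every row of a cube
despike_matrix <- function(X, window = 7L, z = 8) {
  t(apply(X, 1L, despike, window = window, z = z))
}

#' airPLS baseline correction
#'
#' Adaptive iteratively reweighted penalized least squares. The baseline
#' solves the weighted Whittaker system (second-difference smoothness
#' penalty, per-band weights `w`): minimize
#' `sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, differences = 2))^2)`.
#' Weights are re-estimated each iteration: `w_i = 0` where `y_i >= z_i`
#' (signal above the baseline is treated as peak), otherwise
#' `exp(t * |d_i| / |d|)` with `d` the negative part of the residual and
#' `t` the iteration index. Iteration stops when `|d| < ratio * |y|`.
#'
#' @param s A [raman_spectrum] or numeric vector.
#' @param lambda Smoothness penalty (> 0); default 1e5 suits axes of
#'   about 1000 bands.
#' @param max_iter Maximum reweighting iterations (default 15).
#' @param ratio Termination ratio (default 0.001).
#' @return Object of class `baseline_fit`: `baseline`, `corrected`
#'   (input - baseline, exactly), `iterations`, `converged`, `lambda`,
#'   `ratio`. Non-convergence returns the best iterate with
#'   `converged = FALSE`, never an error.
#' @export
airpls <- function(s, lambda = 1e5, max_iter = 15L, ratio = 0.001) {
  y <- if (inherits(s, "raman_spectrum")) s$intensity else as.numeric(s)
  if (lambda <= 0) stop("lambda must be positive")
  L <- length(y)
  abs_y <- sum(abs(y))
  if (abs_y == 0) {
    return(structure(list(baseline = numeric(L), corrected = numeric(L),
                          iterations = 0L, converged = TRUE,
                          lambda = lambda, ratio = ratio),
                     class = "baseline_fit"))
  }
  w <- rep(1, L)
  z <- numeric(L)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    z <- whittaker_solve(y, w, lambda)
    d <- y - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn < ratio * abs_y) {
      converged <- TRUE
      break
    }
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
  }
  structure(list(baseline = z, corrected = y - z, iterations = it,
                 converged = converged, lambda = lambda, ratio = ratio),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %d bands, lambda %.3g, %d iteration(s), %s\n",
              length(x$baseline), x$lambda, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# baseline-correct every row; returns corrected matrix
airpls_matrix <- function(X, lambda = 1e5, max_iter = 15L, ratio = 0.001) {
  t(apply(X, 1L, function(y) airpls(y, lambda, max_iter, ratio)$corrected))
}

#' PCA denoising of a spectrum set or map
#'
#' Mean-centered PCA; the reconstruction keeps the smaller of (number of
#' components reaching `target_variance`, `max_components`) and projects
#' back into the original space. With the defaults this is "first three
#' PCs, provided they explain more than 99.99% of the variance".
#'
#' @param x A [raman_map], list of [raman_spectrum], or matrix (rows =
#'   spectra); at least 2 spectra.
#' @param target_variance Cumulative explained-variance target.
#' @param max_components Hard cap on retained components (default 3).
#' @return List with `data` (denoised object, same type as input) and
#'   `report` (class `denoise_report`: `n_components`,
#'   `explained_variance`, `residual_variance`).
#' @export
pca_denoise <- function(x, target_variance = 0.9999, max_components = 3L) {
  X <- spectra_matrix(x)
  if (nrow(X) < 2L) stop("PCA denoising needs at least 2 spectra")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  total <- sum(Xc^2)
  if (total <= .Machine$double.eps * length(Xc)) {
    warning("spectra are identical: variance is zero, returning input unchanged")
    rep <- structure(list(n_components = 0L, explained_variance = NA_real_,
                          residual_variance = NA_real_), class = "denoise_report")
    return(list(data = x, report = rep))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(which(cumsum(vf) >= target_variance)[1L], max_components,
               na.rm = TRUE)
  if (is.na(ncomp)) ncomp <- min(length(vf), max_components)
  keep <- seq_len(ncomp)
  recon <- pc$x[, keep, drop = FALSE] %*% t(pc$rotation[, keep, drop = FALSE])
  recon <- sweep(recon, 2L, ctr, `+`)
  explained <- sum(vf[keep])
  rep <- structure(list(n_components = as.integer(ncomp),
                        explained_variance = explained,
                        residual_variance = 1 - explained),
                   class = "denoise_report")
  list(data = replace_intensities(x, recon), report = rep)
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf("<denoise_report> %d component(s), %.6f explained variance\n",
              x$n_components, x$explained_variance))
  invisible(x)
}

# put a modified intensity matrix back into the original container type
replace_intensities <- function(x, X) {
  if (inherits(x, "raman_map")) {
    x$cube <- X
    return(x)
  }
  if (inherits(x, "raman_spectrum")) {
    x$intensity <- as.vector(X)
    return(x)
  }
  if (is.list(x) && length(x) && inherits(x[[1L]], "raman_spectrum")) {
    for (i in seq_along(x)) x[[i]]$intensity <- X[i, ]
    return(x)
  }
  X
}

#' Area normalization
#'
#' Divides each spectrum by its summed intensity so that the bands sum to
#' one, correcting intensity differences due to minute optical-path
#' variation. Negative intensities (possible after baseline subtraction)
#' are clipped to zero before summing so the intensity mass is
#' well-defined.
#'
#' @param x A [raman_spectrum], [raman_map], list of spectra, or matrix.
#' @return Same type, each spectrum summing to 1.
#' @export
area_normalize <- function(x) {
  X <- spectra_matrix(x)
  X[X < 0] <- 0
  sums <- rowSums(X)
  if (any(sums <= 0)) {
    bad <- which(sums <= 0)[1L]
    stop(sprintf("spectrum %d has no positive intensity; area normalization undefined", bad))
  }
  replace_intensities(x, X / sums)
}

#' Maximum normalization to \[0, 1\]
#'
#' Divides each spectrum (and each reference-set row) by its own maximum,
#' the scaling applied to both the pixel matrix and the reference matrix
#' before spectral unmixing.
#'
#' @param x A [raman_spectrum], [raman_map], [reference_set], list of
#'   spectra, or matrix.
#' @return Same type, every row with maximum exactly 1.
#' @export
max_normalize <- function(x) {
  if (inherits(x, "reference_set")) {
    m <- apply(x$spectra, 1L, max)
    if (any(m <= 0)) stop(sprintf("component '%s' has non-positive maximum",
                                  x$names[which(m <= 0)[1L]]))
    x$spectra <- x$spectra / m
    return(x)
  }
  X <- spectra_matrix(x)
  m <- apply(X, 1L, max)
  if (any(m <= 0)) {
    bad <- which(m <= 0)[1L]
    stop(sprintf("spectrum %d has non-positive maximum; cannot max-normalize", bad))
  }
  replace_intensities(x, X / m)
}

#' Full noise-reduction chain for a map
#'
#' Applies, in order: background segmentation, despiking, PCA denoising,
#' airPLS baseline correction, and an optional normalization. Only
#' foreground pixels are denoised and baseline-corrected; background
#' pixels pass through unchanged. Each stage can be switched off.
#'
#' Denoising precedes baseline correction here because the baseline fit
#' is nonlinear: run on noisy spectra it tracks the pixel noise floor and
#' erodes weak peaks, whereas the retained principal-component subspace
#' (first three PCs by default, matching the rank of a three-component
#' mixture plus one background mode) estimates each pixel's smooth
#' fluorescence along with its peaks at map-level precision.
#'
#' @param map A [raman_map].
#' @param segment,despike,baseline,denoise Logical stage switches.
#' @param normalize `"none"`, `"area"` or `"max"`; normalization of the
#'   foreground spectra after the chain.
#' @param seg_strategy,band_window Passed to [segment_background()].
#' @param window,z Passed to [despike()].
#' @param lambda,max_iter,ratio Passed to [airpls()].
#' @param target_variance,max_components Passed to [pca_denoise()]. The
#'   pipeline default (`target_variance = 1`) makes the component count
#'   the binding rule: the first `max_components` PCs are kept.
#' @return List with `map` (processed [raman_map], mask updated when
#'   segmentation ran) and `reports` (per-stage summaries).
#' @export
preprocess_map <- function(map, segment = TRUE, despike = TRUE, baseline = TRUE,
                           denoise = TRUE, normalize = c("none", "area", "max"),
                           seg_strategy = "otsu", band_window = NULL,
                           window = 7L, z = 8, lambda = 1e5, max_iter = 15L,
                           ratio = 0.001, target_variance = 1,
                           max_components = 3L) {
  stopifnot(inherits(map, "raman_map"))
  normalize <- match.arg(normalize)
  reports <- list()
  if (segment) {
    map$mask <- segment_background(map, strategy = seg_strategy,
                                   band_window = band_window)
    reports$segmentation <- list(strategy = seg_strategy,
                                 foreground = sum(map$mask),
                                 background = sum(!map$mask))
  }
  fg <- which(map$mask)
  if (!length(fg)) return(list(map = map, reports = reports))
  X <- map$cube[fg, , drop = FALSE]
  if (despike) {
    X <- despike_matrix(X, window = window, z = z)
    reports$despike <- list(window = window, z = z)
  }
  if (denoise && length(fg) >= 2L) {
    dn <- pca_denoise(X, target_variance = target_variance,
                      max_components = max_components)
    X <- dn$data
    reports$denoise <- dn$report
  }
  if (baseline) {
    X <- airpls_matrix(X, lambda = lambda, max_iter = max_iter, ratio = ratio)
    reports$baseline <- list(lambda = lambda, max_iter = max_iter, ratio = ratio)
  }
  if (normalize == "area") X <- area_normalize(X)
  if (normalize == "max") X <- max_normalize(X)
  reports$normalize <- normalize
  map$cube[fg, ] <- X
  map$meta$preprocessing <- reports
  list(map = map, reports = reports)
}
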
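# Discrete wavelet transform with single-branch reconstruction.
#
# A spectrum is decomposed at level 8 into nine coefficient sets
# (A8, D8, ..., D1); reconstructing from one set with all others zeroed
# yields one "branch" per frequency band of the signal. The branches sum
# to the input (perfect reconstruction), so low-frequency fluorescence
# (A8/D8) and high-frequency noise (D1/D2) are separated from the
# Raman-peak-scale structure carried by mid-level branches such as D6.
#
# Boundary handling is half-sample symmetric extension; reconstructions
# are truncated to the input length. Orthogonal Daubechies filter banks
# are built in (standard published coefficients).

DB_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780794, 0.48296291314453416),
  db4 = c(-0.01059740178506903, 0.0328830116668852, 0.03084138183556076,
          -0.18703481171909309, -0.02798376941685985, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933,
          -0.00039174037337694705, -0.0048703529934515741,
          0.0087460940474057766, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.00047248457391328279,
          -0.28401554296154691, -0.015829105256349306,
          0.58535468365420673, 0.67563073629728976,
          0.31287159091429995, 0.054415842243104008)
)

wavelet_filters <- function(family) {
  lo <- DB_FILTERS[[family]]
  if (is.null(lo))
    stop(sprintf("unknown wavelet family '%s' (available: %s)",
                 family, paste(names(DB_FILTERS), collapse = ", ")))
  rev_lo <- rev(lo)
  dec_hi <- rev_lo * (-1)^seq_along(lo)
  list(dec_lo = lo, dec_hi = dec_hi, rec_lo = rev_lo, rec_hi = rev(dec_hi),
       length = length(lo))
}

conv_full <- function(a, b) stats::convolve(a, rev(b), type = "open")

# one analysis step: symmetric extension, filter, dyadic downsample
dwt_step <- function(x, flt) {
  n <- length(x); f <- flt$length
  ext <- c(rev(x[seq_len(f - 1L)]), x, rev(x[(n - f + 2L):n]))
  keep <- floor((n + f - 1L) / 2L)
  idx <- seq(f + 1L, by = 2L, length.out = keep)
  list(cA = conv_full(ext, flt$dec_lo)[idx],
       cD = conv_full(ext, flt$dec_hi)[idx])
}

# one synthesis step, truncated to out_len
idwt_step <- function(cA, cD, flt, out_len) {
  m <- length(cA); f <- flt$length
  up <- function(cc) { u <- numeric(2L * m); u[seq(1L, 2L * m, 2L)] <- cc; u }
  full <- conv_full(up(cA), flt$rec_lo) + conv_full(up(cD), flt$rec_hi)
  full[(f - 1L):(f - 2L + out_len)]
}

# multilevel analysis; returns list(coeffs = list(A<level>, D<level>..D1),
# lengths of the signal at each level for exact inversion)
wavedec <- function(x, flt, level) {
  lens <- integer(level)
  details <- vector("list", level)
  cur <- x
  for (l in seq_len(level)) {
    lens[l] <- length(cur)
    st <- dwt_step(cur, flt)
    details[[l]] <- st$cD        # details[[l]] is D<l>
    cur <- st$cA
  }
  list(approx = cur, details = details, lengths = lens)
}

waverec <- function(approx, details, lens, flt) {
  cur <- approx
  for (l in rev(seq_along(details)))
    cur <- idwt_step(cur, details[[l]], flt, lens[l])
  cur
}

#' Level-`level` single-branch wavelet decomposition of a spectrum
#'
#' Decomposes the signal into `level + 1` coefficient sets (one
#' approximation, `level` details) and reconstructs each set separately
#' with all other sets zeroed. The returned branches form an additive
#' decomposition: `A<level> + D1 + ... + D<level>` equals the input to
#' machine precision.
#'
#' @param s A [raman_spectrum] or numeric vector of length `L >= 2^level`.
#' @param family Wavelet family (default `"db4"`); one of `haar`, `db2`,
#'   `db4`, `db8`.
#' @param level Decomposition level (default 8).
#' @return Object of class `wavelet_branches`: `branches` (named list
#'   `A8, D1..D8` of length-L signals for the default level), `family`,
#'   `level`, `L`.
#' @export
decompose_branches <- function(s, family = "db4", level = 8L) {
  x <- if (inherits(s, "raman_spectrum")) s$intensity else as.numeric(s)
  level <- as.integer(level)
  L <- length(x)
  if (L < 2^level)
    stop(sprintf("signal length %d supports at most level %d (need L >= 2^level)",
                 L, max(0L, floor(log2(L)))))
  flt <- wavelet_filters(family)
  dec <- wavedec(x, flt, level)
  zero_details <- lapply(dec$details, function(d) numeric(length(d)))
  branches <- vector("list", level + 1L)
  names(branches) <- c(paste0("A", level), paste0("D", seq_len(level)))
  branches[[paste0("A", level)]] <-
    waverec(dec$approx, zero_details, dec$lengths, flt)
  for (l in seq_len(level)) {
    det <- zero_details
    det[[l]] <- dec$details[[l]]
    branches[[paste0("D", l)]] <-
      waverec(numeric(length(dec$approx)), det, dec$lengths, flt)
  }
  structure(list(branches = branches, family = family, level = level, L = L),
            class = "wavelet_branches")
}

#' @export
print.wavelet_branches <- function(x, ...) {
  cat(sprintf("<wavelet_branches> %s level %d, %d branches of length %d\n",
              x$family, x$level, length(x$branches), x$L))
  invisible(x)
}

branch_names <- function(level) c(paste0("A", level), paste0("D", seq_len(level)))

# reconstruct a single named branch without building the other eight
single_branch_vec <- function(x, branch, family, level) {
  flt <- wavelet_filters(family)
  dec <- wavedec(x, flt, level)
  zero <- lapply(dec$details, function(d) numeric(length(d)))
  if (branch == paste0("A", level))
    return(waverec(dec$approx, zero, dec$lengths, flt))
  l <- as.integer(sub("^D", "", branch))
  det <- zero
  det[[l]] <- dec$details[[l]]
  waverec(numeric(length(dec$approx)), det, dec$lengths, flt)
}

#' Extract one wavelet branch from a spectrum set or map
#'
#' Applies [decompose_branches()] to every spectrum (or every foreground
#' map pixel) and keeps only the named branch, preserving the container
#' shape, axis and mask. `"D6"` is the default feature signal: at level 8
#' it suppresses both high-frequency noise (D1-D2) and the low-frequency
#' fluorescence background (A8/D8) while retaining Raman-peak-scale
#' structure.
#'
#' @param x A [raman_spectrum], list of spectra, [raman_map], or matrix.
#' @param branch Branch id among `A<level>, D1..D<level>`.
#' @param family,level Passed to [decompose_branches()].
#' @return Same type as the input with intensities replaced by the branch
#'   signal. Background pixels of a map are left unchanged.
#' @export
extract_branch <- function(x, branch = "D6", family = "db4", level = 8L) {
  if (!branch %in% branch_names(level))
    stop(sprintf("unknown branch '%s' (expected one of %s)", branch,
                 paste(branch_names(level), collapse = ", ")))
  one <- function(v) single_branch_vec(v, branch, family, level)
  if (inherits(x, "raman_spectrum")) {
    x$intensity <- one(x$intensity)
    x$meta$wavelet <- list(branch = branch, family = family, level = level)
    return(x)
  }
  if (inherits(x, "raman_map")) {
    fg <- which(x$mask)
    for (i in fg) x$cube[i, ] <- one(x$cube[i, ])
    x$meta$wavelet <- list(branch = branch, family = family, level = level)
    return(x)
  }
  X <- spectra_matrix(x)
  out <- t(apply(X, 1L, one))
  replace_intensities(x, out)
}

#' Image of one wavelet branch at one band
#'
#' Per-pixel branch intensity at the axis point nearest the requested
#' wavenumber; masked (background) pixels are absent (`NA`).
#'
#' @param map A [raman_map].
#' @param branch Branch id (see [extract_branch()]).
#' @param wavenumber Band, cm^-1 (must lie inside the axis).
#' @param family,level Passed to [decompose_branches()].
#' @return `ny x nx` numeric matrix.
#' @export
branch_band_image <- function(map, branch, wavenumber, family = "db4",
                              level = 8L) {
  stopifnot(inherits(map, "raman_map"))
  j <- band_index(map$wavenumber, wavenumber)
  if (!branch %in% branch_names(level))
    stop(sprintf("unknown branch '%s' (expected one of %s)", branch,
                 paste(branch_names(level), collapse = ", ")))
  vals <- rep(NA_real_, nrow(map$cube))
  for (i in which(map$mask))
    vals[i] <- single_branch_vec(map$cube[i, ], branch, family, level)[j]
  matrix(vals, map$ny, map$nx, byrow = TRUE)
}
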
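# Fully constrained least-squares (FCLS) spectral unmixing.
#
# Each foreground pixel spectrum d is decomposed against the k reference
# spectra P (rows) by minimizing ||d - P' c||^2 subject to the abundance
# sum-to-one constraint (sum c = 1) and the non-negativity constraint
# (c >= 0). The solver is an active-set scheme: start from the
# sum-to-one-constrained least-squares solution via a Lagrange
# multiplier, iteratively clamp the most negative abundance to zero and
# re-solve on the remaining free set, releasing clamped components whose
# KKT multiplier turns negative, until the KKT conditions hold.

# KKT system over the free set: minimize c'Qc - 2 b'c s.t. sum(c) = 1
solve_equality_ls <- function(Q, b) {
  kf <- length(b)
  A <- rbind(cbind(2 * Q, 1), c(rep(1, kf), 0))
  rhs <- c(2 * b, 1)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warning("rank-deficient reference set: using minimum-norm solution")
    as.vector(MASS::ginv(A) %*% rhs)
  })
  list(c = sol[seq_len(kf)], lambda = sol[kf + 1L])
}

#' FCLS abundance estimate for one spectrum
#'
#' @param d A [raman_spectrum] or numeric intensity vector.
#' @param P A [reference_set] or `k x L` matrix of component spectra.
#'   By convention both `d` and `P` are max-normalized to \[0, 1\] before
#'   unmixing (see [max_normalize()]); the solver itself accepts any
#'   scale.
#' @return List with `abundance` (named length-k simplex vector),
#'   `residual_norm` (L2 norm of `d - P'c`) and `residual` (per-band
#'   residual vector).
#' @export
fcls_pixel <- function(d, P) {
  y <- if (inherits(d, "raman_spectrum")) d$intensity else as.numeric(d)
  M <- if (inherits(P, "reference_set")) P$spectra else as.matrix(P)
  k <- nrow(M); L <- ncol(M)
  if (length(y) != L) stop("spectrum and references disagree in band count")
  if (k > L) stop(sprintf("more components (%d) than bands (%d)", k, L))
  nm <- rownames(M) %||% paste0("component", seq_len(k))
  if (k == 1L) {
    res <- y - as.vector(M)
    return(list(abundance = stats::setNames(1, nm),
                residual_norm = sqrt(sum(res^2)), residual = res))
  }
  Q <- tcrossprod(M)            # k x k
  b <- as.vector(M %*% y)
  free <- rep(TRUE, k)
  cvec <- numeric(k)
  tol <- 1e-12 * max(1, max(abs(Q)))
  for (iter in seq_len(3L * k + 10L)) {
    sol <- solve_equality_ls(Q[free, free, drop = FALSE], b[free])
    cf <- sol$c
    if (min(cf) < -tol && sum(free) > 1L) {
      # clamp the most negative abundance to zero (active set grows)
      idx_free <- which(free)
      free[idx_free[which.min(cf)]] <- FALSE
      next
    }
    cvec[] <- 0
    cvec[free] <- pmax(cf, 0)
    # KKT multipliers of the clamped components: mu_j = g_j - lambda,
    # with g = gradient of the objective and lambda the equality multiplier
    g <- 2 * (as.vector(Q %*% cvec) - b)
    lambda <- mean(g[free])
    mu <- g - lambda
    clamped <- which(!free)
    if (!length(clamped) || min(mu[clamped]) >= -1e-10 * max(1, max(abs(g)))) break
    free[clamped[which.min(mu[clamped])]] <- TRUE
  }
  cvec <- cvec / sum(cvec)
  res <- y - as.vector(crossprod(M, cvec))
  list(abundance = stats::setNames(cvec, nm),
       residual_norm = sqrt(sum(res^2)), residual = res)
}

#' Unmix every foreground pixel of a map
#'
#' Applies [fcls_pixel()] to each foreground pixel. Background pixels
#' carry no abundance (`NA` rows). Pixels whose residual norm exceeds the
#' `failure_quantile` of foreground residuals are flagged as unmixing
#' failures but never dropped.
#'
#' @param map A (preprocessed) [raman_map].
#' @param refs A [reference_set] on the identical axis (resample first if
#'   needed).
#' @param normalize `"none"` to unmix intensities as given, or `"max"` to
#'   max-normalize both pixel spectra and references to \[0, 1\] first
#'   (the convention used for real maps, where acquisition scale is
#'   arbitrary).
#' @param failure_quantile Quantile of residual norms above which a pixel
#'   is flagged (default 0.99).
#' @return Object of class `abundance_result`: `abundance`
#'   (`(nx*ny) x k`, simplex rows on the foreground), `calibrated`
#'   (filled by [calibrate()]), `residual_norm`, `flagged`, `references`,
#'   `nx`, `ny`, `mask`, `W`.
#' @export
unmix_map <- function(map, refs, normalize = c("none", "max"),
                      failure_quantile = 0.99) {
  stopifnot(inherits(map, "raman_map"), inherits(refs, "reference_set"))
  normalize <- match.arg(normalize)
  if (length(map$wavenumber) != length(refs$wavenumber) ||
      max(abs(map$wavenumber - refs$wavenumber)) > 1e-9)
    stop("map and reference axes differ; use resample_to_axis() first")
  M <- refs$spectra
  cube <- map$cube
  if (normalize == "max") {
    M <- M / apply(M, 1L, max)
    fg_max <- apply(cube, 1L, max)
    ok <- fg_max > 0
    cube[ok, ] <- cube[ok, , drop = FALSE] / fg_max[ok]
  }
  k <- nrow(M)
  npix <- nrow(cube)
  ab <- matrix(NA_real_, npix, k, dimnames = list(NULL, refs$names))
  rn <- rep(NA_real_, npix)
  for (i in which(map$mask)) {
    f <- fcls_pixel(cube[i, ], M)
    ab[i, ] <- f$abundance
    rn[i] <- f$residual_norm
  }
  flagged <- rep(FALSE, npix)
  if (any(map$mask)) {
    thr <- stats::quantile(rn[map$mask], failure_quantile, names = FALSE)
    flagged[map$mask] <- rn[map$mask] > thr
  }
  structure(list(abundance = ab, calibrated = NULL, residual_norm = rn,
                 flagged = flagged, references = refs$names,
                 nx = map$nx, ny = map$ny, mask = map$mask, W = NULL,
                 normalize = normalize),
            class = "abundance_result")
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(sprintf("<abundance_result> %d x %d pixels, %d components (%s), %d unmixed%s\n",
              x$nx, x$ny, ncol(x$abundance),
              paste(x$references, collapse = ", "), sum(x$mask),
              if (!is.null(x$W)) sprintf(", calibrated to W = %.4g%% d.b.", x$W) else ""))
  invisible(x)
}

#' Calibrate abundance fractions to concentrations
#'
#' Multiplies each abundance fraction by `W`, the combined dry-base
#' content (percent) of all k components from laboratory analysis, so
#' each pixel's calibrated concentrations sum to `W`.
#'
#' @param result An [unmix_map()] result.
#' @param W Total component content, percent dry base (> 0); e.g. 77.2
#'   for untreated and 53.4 for alkali-treated rice straw.
#' @return The result with `calibrated = abundance * W` and `W` recorded;
#'   `abundance` itself is unchanged.
#' @export
calibrate <- function(result, W) {
  stopifnot(inherits(result, "abundance_result"))
  if (!is.numeric(W) || length(W) != 1L || W <= 0)
    stop("W must be a positive scalar (percent dry base)")
  result$calibrated <- result$abundance * W
  result$W <- W
  result
}
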
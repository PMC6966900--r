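# Shared fixtures, all built in code. Heavier objects are memoised so a
# single test run pays for them once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_components <- function() memo("components", default_components())

fix_refs <- function() fix_components()$references

# references with their fluorescence removed by the same airPLS settings
# used on map pixels (the matched-correction convention)
fix_refs_corrected <- function() memo("refs_bc", {
  refs <- fix_refs()
  refs$spectra <- t(apply(refs$spectra, 1L, function(y) airpls(y)$corrected))
  refs
})

# a small analytic Gaussian peak on an arbitrary axis
gauss_peak <- function(axis, center, width, height = 1) {
  height * exp(-0.5 * ((axis - center) / width)^2)
}

# tiny deterministic map: 2 x 2 pixels, 6 bands
tiny_map <- function() {
  ax <- seq(600, 650, by = 10)
  cube <- matrix(as.numeric(1:24), 4, 6)
  raman_map(ax, cube, nx = 2, ny = 2, spacing_um = 2.5,
            meta = list(note = "tiny fixture"))
}

# small labeled spot dataset for classifier tests (fast: few samples)
fix_small_spots <- function() memo("small_spots", {
  make_spot_dataset(n_untreated = 40, n_treated = 40, seed = 101)
})

# the full-size spot dataset at the study's class sizes (235 + 339)
fix_spots_full <- function() memo("spots_full", make_spot_dataset(seed = 1))

# independent brute-force FCLS oracle: enumerate every support (subset of
# components allowed to be non-zero), solve the equality-constrained LS
# on that support in closed form, keep the best feasible candidate.
fcls_enumerate <- function(d, P) {
  k <- nrow(P)
  Q <- tcrossprod(P)
  b <- as.vector(P %*% d)
  best <- NULL
  best_obj <- Inf
  for (m in seq_len(2^k - 1L)) {
    sel <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
    kf <- length(sel)
    A <- rbind(cbind(2 * Q[sel, sel, drop = FALSE], 1), c(rep(1, kf), 0))
    sol <- tryCatch(solve(A, c(2 * b[sel], 1)), error = function(e) NULL)
    if (is.null(sol)) next
    cf <- sol[seq_len(kf)]
    if (any(cf < -1e-10)) next
    cc <- numeric(k); cc[sel] <- pmax(cf, 0)
    obj <- sum(cc * (Q %*% cc)) - 2 * sum(b * cc)
    if (obj < best_obj - 1e-15) { best_obj <- obj; best <- cc }
  }
  best
}

# quadprog reference solution (general QP oracle)
fcls_qp <- function(d, P) {
  k <- nrow(P)
  Q <- tcrossprod(P)
  b <- as.vector(P %*% d)
  quadprog::solve.QP(2 * Q + diag(1e-12, k), 2 * b,
                     cbind(rep(1, k), diag(k)), c(1, rep(0, k)),
                     meq = 1)$solution
}
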
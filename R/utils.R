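# internal helpers shared across modules

# Run code under a fixed RNG state, restoring the caller's stream afterwards.
# All stochastic functions in the package route their randomness through this
# so that a seed argument never leaks into global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Otsu's threshold on a numeric score vector: maximize between-class variance
# over a histogram of the scores.
otsu_threshold <- function(scores, n_bins = 256L) {
  scores <- scores[is.finite(scores)]
  rng <- range(scores)
  if (diff(rng) <= 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(scores, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for threshold after each bin
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
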
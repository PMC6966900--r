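# Noise-reduction stages: segmentation, despiking, airPLS, PCA
# denoising, normalizations, and the chain invariants.

test_that("manual threshold splits a two-pixel map", {
  ax <- seq(600, 650, 10)
  m <- raman_map(ax, rbind(rep(0, 6), rep(10, 6)), 2, 1)
  expect_identical(segment_background(m, "manual", tau = 5), c(FALSE, TRUE))
})

test_that("otsu masks out at least 95% of true background on a tile scene", {
  sc <- render_scene("tiles", c(24, 18), seed = 30)
  mask <- segment_background(sc$map, "otsu")
  bg <- sc$truth_labels == "background"
  expect_gte(mean(!mask[bg]), 0.95)
  expect_gte(mean(mask[!bg]), 0.95)
})

test_that("a uniform map yields a warning and an all-foreground mask", {
  ax <- seq(600, 650, 10)
  m <- raman_map(ax, matrix(1, 4, 6), 2, 2)
  expect_warning(mask <- segment_background(m, "manual", tau = 5),
                 "one side")
  expect_true(all(mask))
})

test_that("quantile strategy thresholds at the requested quantile", {
  ax <- seq(600, 650, 10)
  m <- raman_map(ax, outer(1:4, rep(1, 6)), 2, 2)
  expect_identical(segment_background(m, "quantile", q = 0.5),
                   c(FALSE, FALSE, TRUE, TRUE))
})

test_that("despike removes a lone 100x spike and touches nothing else", {
  y <- rep(1, 101)
  y[51] <- 100
  out <- despike(y)
  expect_equal(out[51], 1)
  expect_equal(out[-51], y[-51])
})

test_that("despike leaves a clean analytic peak untouched at z = 8", {
  ax <- seq_len(401)
  y <- gauss_peak(ax, 200, 15)
  expect_equal(despike(y, z = 8), y)
})

test_that("two adjacent spikes are both removed with window >= 5", {
  y <- gauss_peak(seq_len(201), 100, 20) + 0.2
  y[c(60, 61)] <- y[c(60, 61)] + 50
  out <- despike(y, window = 7)
  expect_lt(max(out[c(60, 61)]), 2)
  expect_equal(out[-c(60, 61)], y[-c(60, 61)])
})

test_that("despike is idempotent", {
  set.seed(41)
  y <- gauss_peak(seq_len(301), 150, 20) + rnorm(301, sd = 0.02)
  y[c(30, 200)] <- y[c(30, 200)] + 10
  once <- despike(y)
  expect_identical(despike(once), once)
})

test_that("despike validates its window", {
  expect_error(despike(rep(1, 10), window = 2), "at least 3")
  expect_error(despike(rep(1, 10), window = 4), "odd")
  expect_error(despike(rep(1, 10), window = 11), "smaller than")
})

test_that("airpls recovers a smooth pure baseline (no peaks)", {
  ax <- default_axis()
  y <- 2 + 0.5 * ((ax - 580) / 1000)^2
  fit <- airpls(y)
  expect_lt(max(abs(fit$corrected)), 0.01 * diff(range(y)) + 1e-6)
  expect_true(fit$converged)
})

test_that("airpls of the zero spectrum is zero", {
  fit <- airpls(numeric(500))
  expect_equal(fit$baseline, numeric(500))
  expect_equal(fit$corrected, numeric(500))
  expect_true(fit$converged)
})

test_that("airpls separates three peaks from a quadratic baseline", {
  ax <- default_axis()
  base <- 1 + 2 * ((ax - 580) / 2482)^2
  peaks <- gauss_peak(ax, 1089, 10) + 0.7 * gauss_peak(ax, 1620, 12) +
    0.5 * gauss_peak(ax, 2900, 15)
  fit <- airpls(base + peaks)
  for (ctr in c(1089, 1620, 2900)) {
    j <- band_index(ax, ctr)
    expect_lt(abs(fit$corrected[j] - peaks[j]), 0.05 * peaks[j])
  }
  expect_lt(sqrt(mean((fit$baseline - base)^2)), 0.02 * diff(range(base)))
})

test_that("corrected is exactly input minus baseline", {
  set.seed(42)
  y <- abs(rnorm(500)) + seq(0, 3, length.out = 500)
  fit <- airpls(y)
  expect_identical(fit$corrected, y - fit$baseline)
  expect_equal(fit$baseline + fit$corrected, y, tolerance = 1e-12)
})

test_that("airpls baseline is shift-invariant up to solver tolerance", {
  ax <- default_axis()
  y <- 0.5 * ((ax - 580) / 1000)^2 + gauss_peak(ax, 1200, 12)
  f0 <- airpls(y)
  f5 <- airpls(y + 5)
  expect_lt(max(abs(f5$baseline - (f0$baseline + 5))), 0.02)
})

test_that("airpls validates lambda and reports non-convergence gracefully", {
  expect_error(airpls(rep(1, 100), lambda = 0), "positive")
  set.seed(43)
  fit <- airpls(abs(rnorm(800)) + 2, max_iter = 1L)
  expect_s3_class(fit, "baseline_fit")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 1L)
})

test_that("pca_denoise reproduces exact low-rank data and reports rank", {
  set.seed(44)
  p1 <- gauss_peak(seq_len(300), 100, 10)
  p2 <- gauss_peak(seq_len(300), 200, 15)
  W <- cbind(runif(20), runif(20))
  X <- W %*% rbind(p1, p2)
  out <- pca_denoise(X)
  expect_lte(out$report$n_components, 2L)
  expect_lt(max(abs(out$data - X)), 1e-9)
  # rank-1 case: one component explains everything
  X1 <- runif(10) %*% t(p1)
  out1 <- pca_denoise(X1)
  expect_identical(out1$report$n_components, 1L)
  expect_equal(out1$report$explained_variance, 1, tolerance = 1e-9)
})

test_that("denoise report variance fractions sum to one", {
  set.seed(45)
  X <- matrix(rnorm(40 * 120), 40)
  out <- pca_denoise(X)
  expect_equal(out$report$explained_variance + out$report$residual_variance, 1,
               tolerance = 1e-9)
})

test_that("identical spectra trigger a zero-variance warning", {
  X <- matrix(1, 5, 50)
  expect_warning(out <- pca_denoise(X), "zero")
  expect_identical(out$report$n_components, 0L)
})

test_that("pca_denoise reduces per-band residual noise on a synthetic scene", {
  sigma <- 0.05
  sc <- render_scene("cells", c(15, 15), seed = 46,
                     noise = noise_spec(sigma, 0, c(0, 0), 0))
  fg <- sc$truth_labels != "background"
  clean <- sc$truth_abundance[fg, ] %*% fix_refs()$spectra
  out <- pca_denoise(sc$map$cube[fg, ], target_variance = 1)
  resid_sd <- sqrt(mean((out$data - clean)^2))
  expect_lt(resid_sd, sigma)
})

test_that("area normalization follows the per-spectrum arithmetic", {
  ax <- seq(600, 630, 10)
  s <- raman_spectrum(ax, rep(2, 4))
  expect_equal(area_normalize(s)$intensity, rep(0.25, 4))
  s2 <- raman_spectrum(c(600, 610), c(1, 3))
  expect_equal(area_normalize(s2)$intensity, c(0.25, 0.75))
})

test_that("area normalization sums to one and is idempotent on random spectra", {
  set.seed(47)
  for (i in 1:20) {
    y <- rnorm(200, mean = 2)
    s <- raman_spectrum(seq(600, 600 + 199 * 2, 2), y)
    n1 <- area_normalize(s)
    expect_equal(sum(n1$intensity), 1, tolerance = 1e-12)
    expect_equal(area_normalize(n1)$intensity, n1$intensity, tolerance = 1e-12)
  }
})

test_that("all-zero spectra cannot be area-normalized and are named", {
  X <- rbind(rep(1, 5), rep(0, 5))
  expect_error(area_normalize(X), "spectrum 2")
})

test_that("max normalization scales rows to [0, 1] with max exactly 1", {
  expect_equal(as.vector(max_normalize(matrix(c(2, 4, 8), 1))), c(0.25, 0.5, 1))
  X <- matrix(c(0.2, 0.5, 1.0), 1)
  expect_equal(max_normalize(X), X)          # idempotent on normalized rows
  refs <- max_normalize(fix_refs())
  expect_equal(unname(apply(refs$spectra, 1L, max)), rep(1, 3))
  expect_error(max_normalize(matrix(c(-1, -2), 1)), "non-positive")
})

test_that("the full chain barely perturbs recovery on a zero-nuisance scene", {
  sc <- render_scene("cells", c(20, 20), seed = 48,
                     noise = noise_spec(0, 0, c(0, 0), 0))
  refs_bc <- fix_refs_corrected()
  base <- unmix_map(sc$map, fix_refs(), normalize = "none")
  pp <- preprocess_map(sc$map)
  chained <- unmix_map(pp$map, refs_bc, normalize = "none")
  keep <- sc$truth_labels != "background" & pp$map$mask
  err0 <- mean(abs(base$abundance[keep, ] - sc$truth_abundance[keep, ]))
  err1 <- mean(abs(chained$abundance[keep, ] - sc$truth_abundance[keep, ]))
  expect_lt(abs(err1 - err0), 0.01)
})
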
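# FCLS correctness against independent oracles, map unmixing,
# calibration arithmetic.

test_that("a pure pixel yields a one-hot abundance with zero residual", {
  refs <- fix_refs()
  f <- fcls_pixel(refs$spectra["lignin", ], refs)
  expect_equal(unname(f$abundance), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(f$residual_norm, 1e-9)
})

test_that("a single-component reference forces abundance one", {
  refs <- fix_refs()
  one <- reference_set(refs$wavenumber,
                       refs$spectra["cellulose", , drop = FALSE], "cellulose")
  f <- fcls_pixel(stats::runif(length(refs$wavenumber)), one)
  expect_identical(unname(f$abundance), 1)
})

test_that("a noiseless 0.3/0.5/0.2 mix matches both independent oracles", {
  refs <- fix_refs()
  truth <- c(0.3, 0.5, 0.2)
  d <- as.vector(truth %*% refs$spectra)
  f <- fcls_pixel(d, refs)
  # dense simplex grid (step 0.001), evaluated through the Gram matrix
  Q <- tcrossprod(refs$spectra)
  b <- as.vector(refs$spectra %*% d)
  best <- NULL; best_obj <- Inf
  for (c1 in seq(0, 1, 0.001)) {
    c2 <- seq(0, 1 - c1, 0.001)
    c3 <- 1 - c1 - c2
    obj <- Q[1, 1] * c1^2 + Q[2, 2] * c2^2 + Q[3, 3] * c3^2 +
      2 * (Q[1, 2] * c1 * c2 + Q[1, 3] * c1 * c3 + Q[2, 3] * c2 * c3) -
      2 * (b[1] * c1 + b[2] * c2 + b[3] * c3)
    j <- which.min(obj)
    if (obj[j] < best_obj) { best_obj <- obj[j]; best <- c(c1, c2[j], c3[j]) }
  }
  expect_lte(max(abs(f$abundance - best)), 2e-3)
  expect_lte(max(abs(f$abundance - fcls_qp(d, refs$spectra))), 1e-8)
})

test_that("FCLS agrees with the QP oracle on random instances (k = 2..4)", {
  set.seed(70)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    L <- 200
    P <- matrix(stats::runif(k * L), k)
    d <- stats::runif(L) * 1.5
    f <- fcls_pixel(d, P)
    expect_lte(max(abs(f$abundance - fcls_qp(d, P))), 1e-6)
    expect_lte(max(abs(f$abundance - fcls_enumerate(d, P))), 1e-6)
    expect_lt(abs(sum(f$abundance) - 1), 1e-9)
    expect_gte(min(f$abundance), 0)
  }
})

test_that("the FCLS objective dominates every pure-component vertex fit", {
  set.seed(71)
  refs <- fix_refs()
  L <- length(refs$wavenumber)
  for (i in 1:10) {
    d <- stats::runif(L)
    f <- fcls_pixel(d, refs)
    obj <- sum((d - as.vector(crossprod(refs$spectra, f$abundance)))^2)
    for (j in 1:3) {
      vert <- sum((d - refs$spectra[j, ])^2)
      expect_lte(obj, vert + 1e-9)
    }
  }
})

test_that("degenerate reference sets are handled explicitly", {
  expect_error(fcls_pixel(c(1, 2), matrix(1, 3, 2)), "more components")
  dup <- rbind(c(1, 2, 3, 2), c(1, 2, 3, 2))   # rank-deficient
  expect_warning(f <- fcls_pixel(c(1, 2, 3, 2), dup), "rank-deficient")
  expect_lt(abs(sum(f$abundance) - 1), 1e-9)
})

test_that("zero-nuisance scenes are recovered to machine accuracy (forward/inverse)", {
  sc <- render_scene("cells", c(20, 20), seed = 72,
                     noise = noise_spec(0, 0, c(0, 0), 0))
  res <- unmix_map(sc$map, fix_refs(), normalize = "none")
  fg <- sc$truth_labels != "background"
  expect_lte(mean(abs(res$abundance[fg, ] - sc$truth_abundance[fg, ])), 1e-8)
})

test_that("an all-background map unmixes to an empty abundance set without error", {
  ax <- seq(600, 650, 10)
  m <- raman_map(ax, matrix(1, 4, 6), 2, 2, mask = rep(FALSE, 4))
  refs <- reference_set(ax, matrix(stats::runif(12), 2), c("a", "b"))
  res <- unmix_map(m, refs)
  expect_true(all(is.na(res$abundance)))
  expect_false(any(res$flagged))
})

test_that("axis mismatches between map and references are rejected", {
  ax <- seq(600, 650, 10)
  m <- raman_map(ax, matrix(1, 4, 6), 2, 2)
  refs <- reference_set(ax + 1, matrix(stats::runif(12), 2), c("a", "b"))
  expect_error(unmix_map(m, refs), "resample_to_axis")
})

test_that("abundance rows satisfy the simplex constraints on noisy pixels", {
  set.seed(73)
  sc <- render_scene("random-simplex", c(8, 8), seed = 73)
  res <- unmix_map(sc$map, fix_refs(), normalize = "max")
  ab <- res$abundance[sc$truth_labels != "background", ]
  expect_true(all(abs(rowSums(ab) - 1) < 1e-9))
  expect_true(all(ab >= 0))
})

test_that("calibration is Eq-5 arithmetic: identity at W = 1, scaled rows sum to W", {
  sc <- render_scene("random-simplex", c(5, 5), seed = 74,
                     noise = noise_spec(0, 0, c(0, 0), 0))
  res <- unmix_map(sc$map, fix_refs(), normalize = "none")
  r1 <- calibrate(res, 1)
  expect_equal(r1$calibrated, r1$abundance)
  r2 <- calibrate(res, 77.2)
  expect_equal(unname(rowSums(r2$calibrated)), rep(77.2, 25), tolerance = 1e-9)
  expect_identical(r2$abundance, res$abundance)   # abundance unchanged
  expect_error(calibrate(res, 0), "positive")
  expect_error(calibrate(res, -5), "positive")
})

test_that("a 0.5/0.3/0.2 abundance row calibrated with W = 77.2 gives 38.6/23.16/15.44", {
  row <- c(0.5, 0.3, 0.2)
  expect_equal(row * 77.2, c(38.6, 23.16, 15.44))
  # and through the API
  ax <- seq(600, 640, 10)
  refs <- reference_set(ax, diag(3)[, c(1, 2, 3, 1, 2)] * 1.0, c("c", "h", "l"))
  m <- raman_map(ax, matrix(as.vector(row %*% refs$spectra), 1), 1, 1)
  res <- calibrate(unmix_map(m, refs, normalize = "none"), 77.2)
  expect_equal(unname(res$calibrated[1, ]), c(38.6, 23.16, 15.44),
               tolerance = 1e-8)
})

test_that("recovery error shrinks monotonically with the noise level", {
  refs <- fix_refs()
  err_at <- function(sd) {
    errs <- vapply(c(76, 77), function(seed) {
      sc <- render_scene("cells", c(15, 15), seed = seed,
                         noise = noise_spec(sd, 0, c(0, 0), 0))
      res <- unmix_map(sc$map, refs, normalize = "none")
      fg <- sc$truth_labels != "background"
      mean(abs(res$abundance[fg, ] - sc$truth_abundance[fg, ]))
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0.05, 0.02, 0.01, 0), err_at, numeric(1))
  expect_true(all(diff(errs) < 1e-6))   # decreasing along decreasing sd
  expect_lte(errs[4], 1e-8)
})

test_that("high-residual pixels are flagged but never dropped", {
  sc <- render_scene("cells", c(15, 15), seed = 75)
  res <- unmix_map(sc$map, fix_refs(), normalize = "max")
  fg <- sum(sc$map$mask)
  expect_equal(sum(!is.na(res$abundance[, 1])), fg)
  expect_true(any(res$flagged))
  expect_lte(sum(res$flagged), ceiling(0.02 * fg))
})
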
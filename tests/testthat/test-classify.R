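# PCA clustering, loading-weight band selection, splitting, LDA/KNN and
# the feature grid.

test_that("pca_fit warns on zero-variance input and errors on oversized n_pc", {
  X <- matrix(1, 3, 40)
  expect_warning(p <- pca_fit(X), "undefined")
  expect_true(all(is.na(p$explained)))
  expect_error(pca_fit(matrix(rnorm(20), 4, 5), n_pc = 10), "exceeds")
})

test_that("two PCs explain a rank-2 set completely", {
  set.seed(60)
  base <- rbind(gauss_peak(1:200, 60, 8), gauss_peak(1:200, 140, 12))
  X <- matrix(runif(24), 12, 2) %*% base
  p <- pca_fit(X, n_pc = 3)
  expect_equal(p$cumulative[2], 1, tolerance = 1e-9)
  expect_true(all(diff(p$cumulative) >= -1e-12))
  expect_equal(unname(rowSums(p$loadings^2)), rep(1, 3), tolerance = 1e-9)
})

test_that("pca_fit is deterministic with a fixed sign convention", {
  set.seed(61)
  X <- matrix(rnorm(300), 15, 20)
  p1 <- pca_fit(X, 4); p2 <- pca_fit(X, 4)
  expect_identical(p1$loadings, p2$loadings)
  for (j in seq_len(4))
    expect_gt(p1$loadings[j, which.max(abs(p1$loadings[j, ]))], 0)
})

test_that("spot-scan classes are >= 90% linearly separable in PC1-PC2 of D6", {
  spots <- fix_small_spots()
  d6 <- extract_branch(spots, "D6")
  p <- pca_fit(d6, n_pc = 2)
  labs <- vapply(spots, `[[`, character(1), "label")
  fit <- suppressWarnings(
    stats::glm(I(labs == "treated") ~ p$scores[, 1] + p$scores[, 2],
               family = stats::binomial))
  acc <- mean((stats::fitted(fit) > 0.5) == (labs == "treated"))
  expect_gte(acc, 0.90)
})

test_that("loading-band selection returns nothing below threshold and rejects bad thresholds", {
  p <- structure(list(loadings = matrix(0.02, 2, 50),
                      wavenumber = seq(600, 698, 2),
                      scores = matrix(0, 2, 2)), class = "pca_result")
  expect_identical(select_loading_bands(p), numeric(0))
  expect_error(select_loading_bands(p, threshold = 0), "positive")
})

test_that("planted class markers at 1089 and 1620 are recovered as loading apexes", {
  ax <- default_axis()
  set.seed(62)
  base <- gauss_peak(ax, 900, 20) * 0.3
  mk <- function(cls) {
    bump <- cls * (gauss_peak(ax, 1089, 10) + 0.8 * gauss_peak(ax, 1620, 10))
    raman_spectrum(ax, base + bump + rnorm(length(ax), sd = 0.01))
  }
  spots <- c(lapply(rep(0, 30), mk), lapply(rep(1, 30), mk))
  p <- pca_fit(spots, n_pc = 2)
  apexes <- select_loading_bands(p, threshold = 0.025, pcs = 1:2)
  expect_true(any(abs(apexes - 1089) <= 10))
  expect_true(any(abs(apexes - 1620) <= 10))
})

test_that("stratified 3:1 split hits exact small-sample sizes deterministically", {
  ax <- seq(600, 640, 10)
  mk <- function(lab) raman_spectrum(ax, runif(5), label = lab)
  spots <- c(lapply(1:8, function(i) mk("a")), lapply(1:8, function(i) mk("b")))
  sp <- split_train_test(spots, seed = 5)
  labs <- vapply(sp$train, `[[`, character(1), "label")
  expect_equal(unname(table(labs)), c(6L, 6L), ignore_attr = TRUE)
  expect_length(sp$test, 4L)
  sp2 <- split_train_test(spots, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
})

test_that("a 235 + 339 split lands within one of the exact 3:1 ratio per class", {
  ax <- seq(600, 640, 10)
  mk <- function(lab) raman_spectrum(ax, runif(5), label = lab)
  spots <- c(lapply(seq_len(235), function(i) mk("untreated")),
             lapply(seq_len(339), function(i) mk("treated")))
  sp <- split_train_test(spots, seed = 1)
  labs <- vapply(sp$train, `[[`, character(1), "label")
  expect_lte(abs(sum(labs == "untreated") - 176.25), 1)
  expect_lte(abs(sum(labs == "treated") - 254.25), 1)
})

test_that("degenerate splits are rejected", {
  ax <- seq(600, 640, 10)
  one <- list(raman_spectrum(ax, runif(5), label = "a"),
              raman_spectrum(ax, runif(5), label = "a"))
  expect_error(split_train_test(one), "both classes")
  two <- c(one, list(raman_spectrum(ax, runif(5), label = "b")))
  expect_error(split_train_test(two), "fewer than 2")
})

test_that("LDA is perfect on separated 1-D classes and chance on shuffled labels", {
  set.seed(63)
  tr_x <- matrix(c(rnorm(30, -5), rnorm(30, 5)), ncol = 1)
  tr_y <- rep(c("a", "b"), each = 30)
  te_x <- matrix(c(rnorm(10, -5), rnorm(10, 5)), ncol = 1)
  te_y <- rep(c("a", "b"), each = 10)
  rep1 <- fit_predict_lda(tr_x, tr_y, te_x, te_y)
  expect_equal(rep1$test_accuracy, 100)
  # permutation null: shuffle training labels
  sh <- sample(tr_y)
  rep2 <- fit_predict_lda(tr_x, sh, te_x, sample(te_y))
  expect_lt(abs(rep2$test_accuracy - 50), 35)
})

test_that("an uninformative constant feature predicts the majority class", {
  tr_x <- matrix(1, 30, 1)
  tr_y <- rep(c("a", "b"), c(20, 10))
  te_x <- matrix(1, 10, 1)
  te_y <- rep(c("a", "b"), c(5, 5))
  rep <- fit_predict_lda(tr_x, tr_y, te_x, te_y, shrinkage = 1)
  expect_equal(rep$test_accuracy, 50)   # predicts "a" everywhere
})

test_that("LDA handles collinear wide inputs via shrinkage", {
  set.seed(64)
  L <- 300; n <- 20
  mu <- c(rep(0, 150), rep(1, 150))
  X <- rbind(matrix(rnorm(n * L), n),
             matrix(rnorm(n * L), n) + matrix(mu, n, L, byrow = TRUE))
  y <- rep(c("u", "t"), each = n)
  rep <- fit_predict_lda(X, y, X, y)
  expect_gt(rep$train_accuracy, 90)
  expect_true(attr(rep, "model")$shrinkage > 0)
})

test_that("KNN with k = 1 returns the label of an identical training point", {
  tr_x <- matrix(c(0, 0, 10, 10), 2, byrow = TRUE)
  tr_y <- c("a", "b")
  rep <- fit_predict_knn(tr_x, tr_y, tr_x[2, , drop = FALSE], "b", k = 1)
  expect_equal(rep$test_accuracy, 100)
  expect_equal(rep$train_accuracy, 100)   # own nearest neighbour
})

test_that("KNN matches a brute-force all-pairs vote on a small 2-D set", {
  set.seed(65)
  tr_x <- matrix(rnorm(40), 20, 2)
  tr_y <- rep(c("a", "b"), 10)
  te_x <- matrix(rnorm(16), 8, 2)
  k <- 5
  brute <- apply(te_x, 1, function(q) {
    d <- sqrt(colSums((t(tr_x) - q)^2))
    nn <- order(d)[1:k]
    tab <- table(tr_y[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else tr_y[nn[tr_y[nn] %in% top][1]]
  })
  got <- ramanlcw:::knn_predict(tr_x, tr_y, te_x, k)
  expect_identical(unname(got), unname(brute))
})

test_that("KNN vote ties resolve to the nearest neighbour's class", {
  tr_x <- matrix(c(0, 1, 10, 11), ncol = 1)
  tr_y <- c("a", "a", "b", "b")
  # query at 4: neighbours within k = 4 split 2-2; nearest is "a" (at 1)
  got <- ramanlcw:::knn_predict(tr_x, tr_y, matrix(4), k = 4)
  expect_identical(unname(got), "a")
  expect_error(fit_predict_knn(tr_x, tr_y, tr_x, tr_y, k = 0), "at least 1")
  expect_error(fit_predict_knn(tr_x, tr_y, tr_x, tr_y, k = 9), "exceed")
})

test_that("the feature grid enumerates algorithm x signal x band-set cells", {
  spots <- fix_small_spots()
  grid <- run_feature_grid(spots, algorithms = c("LDA", "KNN"),
                           signals = c("raw", "D6"),
                           band_sets = list(full = "full",
                                            two_band = c(1620, 1089)),
                           seed = 13)
  expect_equal(nrow(grid), 2 * 2 * 2)
  expect_true(all(grid$test_accuracy >= 0 & grid$test_accuracy <= 100))
  expect_true(all(grid$train_accuracy >= 0 & grid$train_accuracy <= 100))
  # reproducible bit-for-bit under the seed
  grid2 <- run_feature_grid(spots, algorithms = c("LDA", "KNN"),
                            signals = c("raw", "D6"),
                            band_sets = list(full = "full",
                                             two_band = c(1620, 1089)),
                            seed = 13)
  expect_identical(grid, grid2)
})

test_that("grid reports serialize and deserialize losslessly", {
  spots <- fix_small_spots()
  grid <- run_feature_grid(spots, algorithms = "KNN", signals = "D6",
                           band_sets = list(two_band = c(1620, 1089)),
                           seed = 13)
  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(grid, p)
  expect_identical(readRDS(p), grid)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_grid(grid, csv)
  wide <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(wide$D6, grid$test_accuracy, tolerance = 1e-9)
})

test_that("the wide grid table has one column per signal", {
  spots <- fix_small_spots()
  grid <- run_feature_grid(spots, algorithms = "KNN",
                           signals = c("raw", "D6"),
                           band_sets = list(full = "full"), seed = 13)
  wide <- format_feature_grid(grid)
  expect_true(all(c("algorithm", "bands", "raw", "D6") %in% names(wide)))
  expect_equal(nrow(wide), 1L)
})
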
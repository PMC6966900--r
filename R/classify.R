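# Unsupervised PCA clustering with loading-weight band analysis, and
# supervised LDA/KNN classification of treated vs untreated spectra over
# a grid of feature signals (raw and wavelet branches) and band sets
# (full range or the 1620 + 1089 cm^-1 fingerprint pair).

#' Mean-centered PCA of a spectrum set
#'
#' Deterministic up to sign; the sign of each component is fixed so that
#' its largest-magnitude loading is positive. Loadings are unit-norm rows.
#'
#' @param x List of [raman_spectrum], [raman_map], or matrix (rows =
#'   spectra).
#' @param n_pc Number of components to keep (default: all available).
#' @return Object of class `pca_result`: `scores` (n x n_pc), `loadings`
#'   (n_pc x L), `explained` and `cumulative` variance fractions,
#'   `center`, `wavenumber` (when the input carries an axis).
#' @export
pca_fit <- function(x, n_pc = NULL) {
  X <- spectra_matrix(x)
  n <- nrow(X); L <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  axis <- tryCatch(spectra_axis(x), error = function(e) NULL)
  if (!is.null(n_pc) && n_pc > min(n, L))
    stop(sprintf("n_pc = %d exceeds min(n, L) = %d", n_pc, min(n, L)))
  total_var <- sum(sweep(X, 2L, colMeans(X))^2)
  if (total_var <= .Machine$double.eps * length(X)) {
    warning("spectra are identical: explained variance is undefined")
    n_pc <- n_pc %||% 1L
    return(structure(list(scores = matrix(0, n, n_pc),
                          loadings = matrix(0, n_pc, L),
                          explained = rep(NA_real_, n_pc),
                          cumulative = rep(NA_real_, n_pc),
                          center = colMeans(X), wavenumber = axis),
                     class = "pca_result"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (is.null(n_pc)) n_pc <- length(pc$sdev)
  n_pc <- min(n_pc, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  sco <- pc$x[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {           # sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = sco, loadings = t(rot),
                 explained = vf[seq_len(n_pc)],
                 cumulative = cumsum(vf)[seq_len(n_pc)],
                 center = pc$center, wavenumber = axis),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d scores x %d PCs; cumulative variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$cumulative[seq_len(min(3, length(x$cumulative)))]),
                    collapse = ", ")))
  invisible(x)
}

#' Bands with large PCA loading weights
#'
#' Finds all axis points where the absolute loading weight exceeds the
#' threshold on any of the selected components, merges them into
#' contiguous runs, and reports each run by its apex wavenumber (the
#' point of largest absolute loading within the run).
#'
#' @param pca A [pca_fit()] result carrying a wavenumber axis.
#' @param threshold Loading-weight threshold (> 0), default 0.025.
#' @param pcs Components to inspect (default first two).
#' @return Numeric vector of apex wavenumbers (cm^-1), one per contiguous
#'   above-threshold region; empty when nothing exceeds the threshold.
#' @export
select_loading_bands <- function(pca, threshold = 0.025, pcs = c(1L, 2L)) {
  stopifnot(inherits(pca, "pca_result"))
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(pca$wavenumber)) stop("pca result carries no wavenumber axis")
  pcs <- pcs[pcs <= nrow(pca$loadings)]
  W <- abs(pca$loadings[pcs, , drop = FALSE])
  peak <- apply(W, 2L, max)             # max |loading| per band over PCs
  above <- peak > threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  apexes <- numeric(0)
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    apexes <- c(apexes, pca$wavenumber[idx[which.max(peak[idx])]])
  }
  apexes
}

#' Stratified train/test split
#'
#' Splits a labeled spectrum set by class at the given train:test ratio
#' (default 3:1), deterministically under the seed. Per-class sizes land
#' within one sample of the exact ratio.
#'
#' @param x List of labeled [raman_spectrum].
#' @param ratio Training fraction (default 0.75, i.e. 3:1).
#' @param seed Integer seed.
#' @return List with `train`, `test` (spectrum lists) and `train_idx`,
#'   `test_idx` (indices into `x`).
#' @export
split_train_test <- function(x, ratio = 0.75, seed = 1) {
  labels <- spectra_labels(x)
  if (anyNA(labels)) stop("every spectrum must carry a class label")
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  if (any(tab < 2L))
    stop(sprintf("class '%s' has fewer than 2 members", names(tab)[tab < 2L][1L]))
  with_seed(seed, {
    train_idx <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_tr <- round(ratio * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(x), train_idx)
    list(train = x[train_idx], test = x[test_idx],
         train_idx = train_idx, test_idx = test_idx)
  })
}

# Ledoit-Wolf-style shrinkage intensity toward a scaled identity target,
# computed from the rows of the (class-centered) data matrix via the
# n x n Gram matrix so it stays cheap for L >> n.
lw_shrinkage <- function(Xc) {
  n <- nrow(Xc); L <- ncol(Xc)
  G <- tcrossprod(Xc)                   # n x n
  trS <- sum(diag(G)) / n
  S_f2 <- sum(G^2) / n^2                # ||S||_F^2
  m <- trS / L
  d2 <- S_f2 / L - m^2
  if (d2 <= 0) return(list(rho = 1, m = m))
  b2bar <- (sum(diag(G)^2) - S_f2 * n) / (n^2 * L)
  rho <- min(max(b2bar, 0) / d2, 1)
  list(rho = rho, m = m)
}

classifier_report <- function(algorithm, signal, bands, ratio, seed,
                              train_pred, train_y, test_pred, test_y, k = NA) {
  structure(list(algorithm = algorithm, signal = signal,
                 bands = bands, split_ratio = ratio, seed = seed, k = k,
                 n_train = length(train_y), n_test = length(test_y),
                 train_accuracy = 100 * mean(train_pred == train_y),
                 test_accuracy = 100 * mean(test_pred == test_y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s on %s/%s: train %.2f%%, test %.2f%%\n",
              x$algorithm, x$signal, x$bands, x$train_accuracy, x$test_accuracy))
  invisible(x)
}

#' Fisher LDA with shrinkage for collinear spectra
#'
#' Gaussian linear discriminant with a pooled within-class covariance.
#' Full-range spectra are strongly collinear (many more bands than
#' samples), so the covariance is shrunk toward a scaled identity with a
#' Ledoit-Wolf-style automatic intensity (`shrinkage = "auto"`); a fixed
#' intensity in \[0, 1\] may be given instead. Falls back to a
#' pseudo-inverse when the shrunk matrix is still singular.
#'
#' @param train_x,test_x Feature matrices (rows = samples).
#' @param train_y,test_y Class labels.
#' @param shrinkage `"auto"` or a number in \[0, 1\].
#' @param signal,bands,ratio,seed Provenance recorded in the report.
#' @return A `classifier_report` with train/test accuracy (%), plus the
#'   fitted discriminant in attribute `"model"`.
#' @export
fit_predict_lda <- function(train_x, train_y, test_x, test_y,
                            shrinkage = "auto", signal = "raw",
                            bands = "full", ratio = 0.75, seed = NA) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  classes <- sort(unique(train_y))
  if (length(classes) < 2L) stop("training set must contain at least 2 classes")
  n <- nrow(train_x); L <- ncol(train_x)
  mus <- matrix(vapply(classes, function(cl)
    colMeans(train_x[train_y == cl, , drop = FALSE]), numeric(L)),
    nrow = length(classes), ncol = L, byrow = TRUE)
  Xc <- train_x - mus[match(train_y, classes), , drop = FALSE]
  S <- crossprod(Xc) / n
  if (identical(shrinkage, "auto")) {
    lw <- lw_shrinkage(Xc)
    rho <- lw$rho; m <- lw$m
  } else {
    rho <- as.numeric(shrinkage)
    m <- mean(diag(S))
  }
  Sg <- (1 - rho) * S
  diag(Sg) <- diag(Sg) + rho * m
  Sinv_mu <- tryCatch(solve(Sg, t(mus)),
                      error = function(e) MASS::ginv(Sg) %*% t(mus))
  priors <- as.numeric(table(factor(train_y, classes))) / n
  const <- -0.5 * colSums(t(mus) * Sinv_mu) + log(priors)
  predict_lda <- function(X) {
    sc <- X %*% Sinv_mu
    sc <- sweep(sc, 2L, const, `+`)
    classes[max.col(sc, ties.method = "first")]
  }
  rep <- classifier_report("LDA", signal, bands, ratio, seed,
                           predict_lda(train_x), train_y,
                           predict_lda(test_x), test_y)
  attr(rep, "model") <- list(classes = classes, Sinv_mu = Sinv_mu,
                             const = const, shrinkage = rho)
  rep
}

#' K-nearest-neighbour classification
#'
#' Euclidean distances on the selected band intensities, majority vote
#' among the k nearest training samples; vote ties are broken by the
#' class of the single nearest neighbour among the tied classes.
#'
#' @param train_x,test_x Feature matrices (rows = samples).
#' @param train_y,test_y Class labels.
#' @param k Number of neighbours (default 5; must satisfy
#'   `1 <= k <= nrow(train_x)`).
#' @param signal,bands,ratio,seed Provenance recorded in the report.
#' @return A `classifier_report` with train/test accuracy (%). Training
#'   accuracy counts each sample as its own nearest neighbour.
#' @export
fit_predict_knn <- function(train_x, train_y, test_x, test_y, k = 5L,
                            signal = "raw", bands = "full", ratio = 0.75,
                            seed = NA) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(train_x)) stop("k cannot exceed the training-set size")
  rep <- classifier_report("KNN", signal, bands, ratio, seed,
                           knn_predict(train_x, train_y, train_x, k),
                           train_y,
                           knn_predict(train_x, train_y, test_x, k),
                           test_y, k = k)
  rep
}

knn_predict <- function(train_x, train_y, query_x, k) {
  # squared Euclidean distances, queries x train
  d2 <- outer(rowSums(query_x^2), rowSums(train_x^2), `+`) -
    2 * tcrossprod(query_x, train_x)
  apply(d2, 1L, function(d) {
    nn <- order(d)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # tie: the nearest neighbour whose class is among the tied classes
    train_y[nn[train_y[nn] %in% top][1L]]
  })
}

# Feature-matrix construction for one grid cell: a signal (raw spectrum
# or one wavelet branch) restricted to a band set.
signal_matrices <- function(spots, signals, family = "db4", level = 8L) {
  X <- spectra_matrix(spots)
  out <- list()
  need_branches <- setdiff(signals, "raw")
  if ("raw" %in% signals) out$raw <- X
  if (length(need_branches)) {
    per <- vector("list", nrow(X))
    for (i in seq_len(nrow(X)))
      per[[i]] <- decompose_branches(X[i, ], family, level)$branches
    for (b in need_branches)
      out[[b]] <- do.call(rbind, lapply(per, function(br) br[[b]]))
  }
  out
}

band_columns <- function(axis, bands) {
  if (identical(bands, "full")) return(seq_along(axis))
  vapply(bands, function(w) band_index(axis, w), integer(1L))
}

#' Run the full algorithm x signal x band-set classification grid
#'
#' One classifier per combination of algorithm (LDA, KNN), feature signal
#' (raw spectrum or one of the nine level-8 wavelet branches) and band
#' set (full range, or an explicit wavenumber pair such as
#' 1620 + 1089 cm^-1). A single stratified 3:1 split, drawn once from the
#' seed, is shared by every grid cell.
#'
#' @param spots List of labeled [raman_spectrum] (e.g. from
#'   [make_spot_dataset()]).
#' @param algorithms Subset of `c("LDA", "KNN")`.
#' @param signals Feature signals among `"raw"`, `"A8"`, `"D1"`..`"D8"`.
#' @param band_sets Named list; each element is `"full"` or a numeric
#'   vector of wavenumbers.
#' @param seed Integer seed for the split.
#' @param k Neighbours for KNN.
#' @param ratio Training fraction.
#' @param family,level Wavelet settings for branch signals.
#' @return Data frame of class `feature_grid`, one row per grid cell,
#'   with train and test accuracy in percent.
#' @export
run_feature_grid <- function(spots, algorithms = c("LDA", "KNN"),
                             signals = c("raw", "A8", paste0("D", 1:8)),
                             band_sets = list(full = "full",
                                              two_band = c(1620, 1089)),
                             seed = 42, k = 5L, ratio = 0.75,
                             family = "db4", level = 8L) {
  labels <- spectra_labels(spots)
  axis <- spectra_axis(spots)
  sp <- split_train_test(spots, ratio = ratio, seed = seed)
  mats <- signal_matrices(spots, signals, family, level)
  rows <- list()
  for (sg in signals) {
    M <- mats[[sg]]
    for (bs in names(band_sets)) {
      cols <- band_columns(axis, band_sets[[bs]])
      tr_x <- M[sp$train_idx, cols, drop = FALSE]
      te_x <- M[sp$test_idx, cols, drop = FALSE]
      tr_y <- labels[sp$train_idx]; te_y <- labels[sp$test_idx]
      for (alg in algorithms) {
        rep <- if (alg == "LDA")
          fit_predict_lda(tr_x, tr_y, te_x, te_y, signal = sg, bands = bs,
                          ratio = ratio, seed = seed)
        else
          fit_predict_knn(tr_x, tr_y, te_x, te_y, k = k, signal = sg,
                          bands = bs, ratio = ratio, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, signal = sg, bands = bs,
          train_accuracy = rep$train_accuracy,
          test_accuracy = rep$test_accuracy,
          n_train = rep$n_train, n_test = rep$n_test,
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_grid", "data.frame")
  out
}

#' Render a feature grid as a wide accuracy table
#'
#' Rows are algorithm x band set, columns are feature signals; cells hold
#' the chosen accuracy in percent.
#'
#' @param grid A [run_feature_grid()] result.
#' @param which `"test"` or `"train"` accuracy.
#' @return Wide data frame.
#' @export
format_feature_grid <- function(grid, which = c("test", "train")) {
  which <- match.arg(which)
  col <- paste0(which, "_accuracy")
  signals <- unique(grid$signal)
  out <- list()
  for (alg in unique(grid$algorithm)) for (bs in unique(grid$bands)) {
    sub <- grid[grid$algorithm == alg & grid$bands == bs, ]
    row <- stats::setNames(as.list(sub[[col]][match(signals, sub$signal)]), signals)
    out[[length(out) + 1L]] <- cbind(data.frame(algorithm = alg, bands = bs),
                                     as.data.frame(row, check.names = FALSE))
  }
  do.call(rbind, out)
}

#' Write a feature grid (long and wide form) to CSV
#'
#' @param grid A [run_feature_grid()] result.
#' @param path Output CSV path (wide accuracy table); the long table is
#'   written next to it with suffix `_long`.
#' @return `path`, invisibly.
#' @export
write_feature_grid <- function(grid, path) {
  utils::write.csv(format_feature_grid(grid), path, row.names = FALSE)
  long_path <- sub("(\\.[^.]+)?$", "_long\\1", path)
  utils::write.csv(as.data.frame(grid), long_path, row.names = FALSE)
  invisible(path)
}
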
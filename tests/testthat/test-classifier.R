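test_that("univariate AUC is the normalized concordant-pair statistic", {
  vals <- c(1, 2, 4, 3, 5)
  labs <- c(FALSE, FALSE, FALSE, TRUE, TRUE)   # positives at 3, 5
  expect_equal(univariate_auc(vals, labs), 5 / 6)

  expect_equal(univariate_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(univariate_auc(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(univariate_auc(1:4, rep(TRUE, 4)), "both classes")

  set.seed(19)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    v <- sample(1:8, n, replace = TRUE)       # ties included
    y <- runif(n) > 0.5
    if (!any(y) || all(y)) y[1:2] <- c(TRUE, FALSE)
    expect_equal(univariate_auc(v, y), bf_auc(v, y), tolerance = 1e-12)
  }
})

test_that("univariate AUC agrees with an off-the-shelf ROC routine", {
  skip_if_not_installed("pROC")
  set.seed(33)
  v <- rnorm(40)
  y <- runif(40) > 0.5
  y[1:2] <- c(TRUE, FALSE)
  expect_equal(univariate_auc(v, y),
               as.numeric(pROC::auc(pROC::roc(y, v, direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("feature selection ranks by folded AUC and prunes correlated features", {
  set.seed(41)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  strong <- rnorm(n) + 2 * y
  dup <- strong                         # |r| = 1 with strong
  weak <- rnorm(n) + 0.3 * y
  noise <- rnorm(n)
  X <- cbind(a_strong = strong, b_dup = dup, c_weak = weak, d_noise = noise)
  sel <- select_features(X, y, k_top = 3)
  expect_equal(sel[1], "a_strong")      # ties broken by name: a before b
  expect_false("b_dup" %in% sel)        # pruned at |r| >= 0.7

  ## orthogonal features: exactly k_top kept
  set.seed(42)
  X2 <- matrix(rnorm(60 * 12), 60, 12,
               dimnames = list(NULL, sprintf("f%02d", 1:12)))
  expect_length(select_features(X2, y, k_top = 10), 10L)

  ## inverted feature is still ranked by folded AUC
  Xinv <- cbind(inv = -strong, d_noise = noise)
  expect_equal(select_features(Xinv, y, k_top = 1), "inv")
})

test_that("greedy admission equals an exhaustive re-check on a constructed table", {
  set.seed(55)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  f1 <- rnorm(n) + 1.5 * y
  f2 <- f1 * 0.95 + rnorm(n, sd = 0.28)          # highly correlated with f1
  f3 <- rnorm(n) + 0.8 * y
  f4 <- rnorm(n) + 0.4 * y
  f5 <- rnorm(n)
  X <- cbind(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5)
  sel <- select_features(X, y, k_top = 4, r_threshold = 0.7)

  ## independent re-implementation of the admission rule
  aucs <- apply(X, 2, function(v) max(bf_auc(v, y), 1 - bf_auc(v, y)))
  ord <- colnames(X)[order(-aucs, colnames(X))]
  kept <- character(0)
  for (f in ord) {
    if (length(kept) >= 4) break
    if (all(abs(cor(X[, f], X[, kept, drop = FALSE])) < 0.7)) kept <- c(kept, f)
  }
  expect_identical(sel, kept)
  expect_true(sum(c("f1", "f2") %in% sel) <= 1)
})

test_that("repeated CV is stratified, deterministic, and leak-free", {
  set.seed(61)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))

  folds <- pkdradiomics:::stratified_folds(y, 5L)
  for (k in 1:5) {
    expect_lte(abs(sum(y[folds == k]) - sum(!y[folds == k])), 1L)
  }

  r1 <- repeated_cv_auc(X, y, folds = 5, repeats = 3, seed = 7)
  r2 <- repeated_cv_auc(X, y, folds = 5, repeats = 3, seed = 7)
  expect_identical(r1, r2)
  expect_length(r1$fold_aucs, 15L)
  expect_true(r1$interval[["low"]] <= r1$mean_auc &&
              r1$mean_auc <= r1$interval[["high"]])

  ## a feature equal to the label is selected and classifies perfectly
  Xleak <- cbind(X, label_copy = as.numeric(y))
  rl <- repeated_cv_auc(Xleak, y, folds = 5, repeats = 2, seed = 7)
  expect_gt(rl$mean_auc, 0.95)
  expect_gt(rl$selection_counts[["label_copy"]], 0)

  ## a feature informative ONLY on held-out rows must not be exploited:
  ## selection sees training rows where it is pure noise, so it can never
  ## outrank a genuinely informative training-set feature
  set.seed(62)
  good <- rnorm(n) + 2.5 * y
  for (rep_i in 1:3) {
    assign <- pkdradiomics:::stratified_folds(y, 5L)
    test_rows <- assign == 1
    sneak <- rnorm(n)
    sneak[test_rows] <- as.numeric(y[test_rows]) * 10
    Xs <- cbind(X, good = good, sneak = sneak)
    sel <- select_features(Xs[!test_rows, ], y[!test_rows], k_top = 10)
    expect_identical(sel[1], "good")
  }

  expect_error(repeated_cv_auc(X[1:8, ], y[1:8], folds = 5, repeats = 1, seed = 1),
               "at least")
})

test_that("random labels give chance-level CV AUC", {
  set.seed(71)
  n <- 80
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(TRUE, FALSE), each = n / 2)[sample(n)]
  r <- repeated_cv_auc(X, y, folds = 5, repeats = 10, seed = 3)
  expect_lt(abs(r$mean_auc - 0.5), 0.1)
})

test_that("auc_grid covers every cell and errors on missing ones", {
  set.seed(81)
  n <- 24
  feat_cols <- feature_name_manifest()$name
  cells <- expand.grid(roi_kind = "noncystic",
                       normalization = c("original", "zscore"),
                       resampling = "down_2.0mm",
                       n_gray_levels = c(8L, 16L),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  store <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    df <- data.frame(case_id = sprintf("c%02d", 1:n),
                     class = rep(c("PKD1", "PKD2"), each = n / 2),
                     site = 1L, roi_kind = cells$roi_kind[i],
                     normalization = cells$normalization[i],
                     resampling = cells$resampling[i],
                     n_gray_levels = cells$n_gray_levels[i],
                     n_degenerate = 0L, stringsAsFactors = FALSE)
    cbind(df, matrix(rnorm(n * 93), n, 93,
                     dimnames = list(NULL, feat_cols)))
  }))
  grid <- auc_grid(store, folds = 4, repeats = 2, seed = 13, expected = cells)
  expect_equal(nrow(grid), 4L)
  expect_true(all(grid$mean_auc >= 0 & grid$mean_auc <= 1))

  grid2 <- auc_grid(store, folds = 4, repeats = 2, seed = 13, expected = cells)
  expect_equal(grid, grid2, ignore_attr = TRUE)

  missing_cells <- rbind(cells, data.frame(roi_kind = "noncystic",
                                           normalization = "reference",
                                           resampling = "down_2.0mm",
                                           n_gray_levels = 8L))
  expect_error(auc_grid(store, folds = 4, repeats = 2, seed = 13,
                        expected = missing_cells), "missing grid cell")
})
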
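#' Rank-based univariate AUC
#'
#' Area under the ROC curve of a single score against binary labels,
#' computed as the normalized Mann-Whitney statistic (concordant pairs, ties
#' counted half).
#'
#' @param values Numeric score vector.
#' @param labels Binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is the positive class).
#' @return Raw AUC in [0, 1] (not orientation-folded).
#' @export
univariate_auc <- function(values, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(values, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels", call. = FALSE)
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("labels must have exactly 2 distinct values", call. = FALSE)
  labels == u[2]
}

folded_auc <- function(values, labels) {
  a <- univariate_auc(values, labels)
  max(a, 1 - a)
}

#' Univariate-AUC feature selection with Pearson pruning
#'
#' Ranks features by orientation-folded univariate AUC (`max(a, 1 - a)`,
#' descending; ties broken by feature name ascending) and admits them
#' greedily: a feature is kept only if its absolute Pearson correlation with
#' every already-kept feature is below `r_threshold`. Stops at `k_top`
#' features or at exhaustion. Zero-variance features are never admitted.
#'
#' @param train_table Numeric matrix or data frame, columns = features.
#' @param labels Binary labels for the rows.
#' @param k_top Maximum number of features to keep (default 10).
#' @param r_threshold Absolute Pearson correlation threshold (default 0.7).
#' @return Character vector of selected feature names, in admission order.
#' @export
select_features <- function(train_table, labels, k_top = 10L, r_threshold = 0.7) {
  X <- as.matrix(train_table)
  sds <- apply(X, 2, stats::sd)
  usable <- colnames(X)[is.finite(sds) & sds > 0]
  if (length(usable) == 0L) return(character(0))
  aucs <- vapply(usable, function(f) folded_auc(X[, f], labels), numeric(1))
  ord <- usable[order(-aucs, usable)]
  kept <- character(0)
  for (f in ord) {
    if (length(kept) >= k_top) break
    if (length(kept) == 0L) {
      kept <- f
    } else {
      r <- suppressWarnings(abs(stats::cor(X[, f], X[, kept, drop = FALSE])))
      if (all(r < r_threshold, na.rm = TRUE)) kept <- c(kept, f)
    }
  }
  kept
}

## Stratified fold assignment: per class, shuffle then deal round-robin, so
## per-fold class imbalance is at most one sample.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validated AUC with in-fold feature selection
#'
#' Stratified k-fold cross-validation repeated `repeats` times. Within each
#' training partition only: univariate-AUC top-`k_top` feature selection
#' with Pearson pruning, z-standardization of the selected columns, and a
#' maximum-likelihood logistic regression fit; the held-out fold is scored
#' by AUC of the predicted probabilities. The summary interval is the 95%
#' normal-theory interval of the mean over all folds x repeats AUCs.
#'
#' @param table Numeric matrix or data frame of features (rows = subjects).
#' @param labels Binary labels.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repetitions (default 10).
#' @param seed Seed controlling all fold assignments.
#' @param k_top,r_threshold Passed to [select_features()].
#' @return A `cv_result`: list(mean_auc, interval = c(low, high), fold_aucs,
#'   selection_counts, folds, repeats, seed).
#' @export
repeated_cv_auc <- function(table, labels, folds = 5L, repeats = 10L, seed,
                            k_top = 10L, r_threshold = 0.7) {
  X <- as.matrix(table)
  y <- as_binary_labels(labels)
  if (min(sum(y), sum(!y)) < folds) {
    stop("each class must have at least `folds` samples", call. = FALSE)
  }
  fold_aucs <- numeric(0)
  sel_counts <- stats::setNames(integer(ncol(X)), colnames(X))
  for (rep_i in seq_len(repeats)) {
    assign <- with_seed(derive_seed(seed, paste0("rep_", rep_i)),
                        stratified_folds(y, folds))
    for (k in seq_len(folds)) {
      tr <- assign != k
      sel <- select_features(X[tr, , drop = FALSE], y[tr],
                             k_top = k_top, r_threshold = r_threshold)
      if (length(sel) == 0L) {
        fold_aucs <- c(fold_aucs, 0.5)
        next
      }
      sel_counts[sel] <- sel_counts[sel] + 1L
      mu <- colMeans(X[tr, sel, drop = FALSE])
      sdv <- apply(X[tr, sel, drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Z <- sweep(sweep(X[, sel, drop = FALSE], 2, mu), 2, sdv, "/")
      df_tr <- data.frame(y = y[tr], Z[tr, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                         family = stats::binomial(),
                                         control = list(maxit = 50)))
      prob <- suppressWarnings(
        stats::predict(fit, newdata = data.frame(Z[!tr, , drop = FALSE]),
                       type = "response"))
      fold_aucs <- c(fold_aucs, univariate_auc(prob, y[!tr]))
    }
  }
  mean_auc <- mean(fold_aucs)
  half <- 1.96 * stats::sd(fold_aucs) / sqrt(length(fold_aucs))
  structure(list(mean_auc = mean_auc,
                 interval = c(low = mean_auc - half, high = mean_auc + half),
                 fold_aucs = fold_aucs, selection_counts = sel_counts,
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' Cross-validated AUC over the full preprocessing grid
#'
#' Runs [repeated_cv_auc()] once per (roi_kind, normalization, resampling,
#' n_gray_levels) cell of a wide feature store, with a deterministic
#' per-cell seed substream.
#'
#' @param feature_store Wide data frame from [extract_feature_table()]:
#'   provenance columns (`case_id`, `class`, `site`, `roi_kind`,
#'   `normalization`, `resampling`, `n_gray_levels`) plus the 93 feature
#'   columns.
#' @param folds,repeats,k_top,r_threshold Passed to [repeated_cv_auc()].
#' @param seed Master seed.
#' @param expected Optional data frame of expected cells (columns
#'   `roi_kind`, `normalization`, `resampling`, `n_gray_levels`); defaults
#'   to all cells present in the store, and errors if any expected cell is
#'   missing.
#' @return Data frame with one row per cell: the setting columns plus
#'   `mean_auc`, `auc_low`, `auc_high`, `n_subjects`; per-cell
#'   `cv_result`s in the `"cv_results"` attribute.
#' @export
auc_grid <- function(feature_store, folds = 5L, repeats = 10L, seed,
                     k_top = 10L, r_threshold = 0.7, expected = NULL) {
  key_cols <- c("roi_kind", "normalization", "resampling", "n_gray_levels")
  present <- unique(feature_store[, key_cols])
  if (!is.null(expected)) {
    pk <- do.call(paste, c(present[key_cols], sep = "|"))
    ek <- do.call(paste, c(expected[key_cols], sep = "|"))
    missing <- setdiff(ek, pk)
    if (length(missing) > 0L) {
      stop(sprintf("missing grid cell(s): %s", paste(missing, collapse = "; ")),
           call. = FALSE)
    }
    present <- expected
  }
  present <- present[order(present$roi_kind, present$normalization,
                           present$resampling, present$n_gray_levels), ,
                     drop = FALSE]
  feat_cols <- feature_name_manifest()$name
  results <- vector("list", nrow(present))
  rows <- vector("list", nrow(present))
  for (i in seq_len(nrow(present))) {
    cell <- present[i, ]
    sub <- feature_store[feature_store$roi_kind == cell$roi_kind &
                         feature_store$normalization == cell$normalization &
                         feature_store$resampling == cell$resampling &
                         feature_store$n_gray_levels == cell$n_gray_levels, ,
                         drop = FALSE]
    cell_key <- paste(cell$roi_kind, cell$normalization, cell$resampling,
                      cell$n_gray_levels, sep = "_")
    cv <- repeated_cv_auc(sub[, feat_cols], sub$class, folds = folds,
                          repeats = repeats,
                          seed = derive_seed(seed, cell_key),
                          k_top = k_top, r_threshold = r_threshold)
    results[[i]] <- cv
    rows[[i]] <- cbind(cell, data.frame(mean_auc = cv$mean_auc,
                                        auc_low = cv$interval[["low"]],
                                        auc_high = cv$interval[["high"]],
                                        n_subjects = nrow(sub)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(results) <- do.call(paste, c(present[key_cols], sep = "|"))
  attr(out, "cv_results") <- results
  out
}
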
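#' Two-way mixed-effects consistency ICC, single rater
#'
#' The ICC(3,1) estimate from the two-way ANOVA decomposition of an n x k
#' rating matrix (rows = observation units, here kidneys; columns = raters,
#' here the normalization arms): `(MSR - MSE) / (MSR + (k - 1) MSE)`, with
#' MSR the mean square for rows and MSE the residual mean square. Because
#' the consistency form ignores fixed rater offsets, a column that is a pure
#' shift of another yields ICC 1. Negative values are reported as computed
#' (no truncation at 0).
#'
#' @param matrix Numeric matrix, n >= 2 rows, k in {2, 3, ...} columns, no
#'   missing cells.
#' @return An `icc_result`: list(icc, ms_rows, ms_error, k, n, category,
#'   degenerate). A matrix whose cells are all identical is flagged
#'   degenerate with `icc = NA`.
#' @export
icc_consistency <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(!is.finite(m))) stop("rating matrix has missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 units and 2 raters", call. = FALSE)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse
  if (denom <= .Machine$double.eps * max(1, abs(grand))^2) {
    return(structure(list(icc = NA_real_, ms_rows = msr, ms_error = mse,
                          k = k, n = n, category = NA_character_,
                          degenerate = TRUE),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / denom
  structure(list(icc = icc, ms_rows = msr, ms_error = mse, k = k, n = n,
                 category = categorize_icc(icc), degenerate = FALSE),
            class = "icc_result")
}

#' Reproducibility category of an ICC value
#'
#' Thresholds: below 0.5 poor, 0.5 up to (excluding) 0.75 moderate, 0.75
#' and above good-to-excellent.
#'
#' @param icc Numeric vector of ICC values (NAs pass through).
#' @return Character vector in {"poor", "moderate", "good_to_excellent"}.
#' @export
categorize_icc <- function(icc) {
  ifelse(is.na(icc), NA_character_,
         ifelse(icc < 0.5, "poor",
                ifelse(icc < 0.75, "moderate", "good_to_excellent")))
}

#' Per-feature ICC report across normalization raters
#'
#' For every feature and every (n_gray_levels, resampling) cell, computes
#' the consistency ICC of the kidneys-by-normalization rating matrix, plus
#' per-cell category fractions over the panel and per-family mean ICC.
#' A rater subset of size 2 yields the pairwise comparison report.
#'
#' @param feature_table Long-format data frame with columns `case_id`,
#'   `normalization`, `resampling`, `n_gray_levels`, `feature`, `value`
#'   (see [feature_table_long()]).
#' @param rater_subset Character vector (length >= 2) of normalization arms.
#' @return List of class `icc_report`: `per_feature` (feature, family,
#'   n_gray_levels, resampling, rater_set, icc, category, degenerate),
#'   `fractions` (per-cell category fractions with degenerate counts), and
#'   `family_means` (per-cell per-family mean ICC).
#' @export
reproducibility_study <- function(feature_table,
                                  rater_subset = c("original", "zscore", "reference")) {
  if (length(rater_subset) < 2L) {
    stop("need at least 2 normalization raters for ICC", call. = FALSE)
  }
  ft <- feature_table[feature_table$normalization %in% rater_subset, , drop = FALSE]
  have <- unique(ft$normalization)
  if (!all(rater_subset %in% have)) {
    stop(sprintf("missing normalization arm(s): %s",
                 paste(setdiff(rater_subset, have), collapse = ", ")),
         call. = FALSE)
  }
  rater_set <- paste(sort(rater_subset), collapse = "+")
  man <- feature_name_manifest()
  cells <- unique(ft[, c("n_gray_levels", "resampling")])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- ft[ft$n_gray_levels == cells$n_gray_levels[ci] &
               ft$resampling == cells$resampling[ci], , drop = FALSE]
    for (f in man$name) {
      sub <- cell[cell$feature == f, , drop = FALSE]
      vals <- tapply(sub$value,
                     list(factor(sub$case_id),
                          factor(sub$normalization, levels = sort(rater_subset))),
                     function(v) v[1])
      if (any(is.na(vals))) {
        stop(sprintf("feature %s: missing cells for %s at %d gray levels / %s",
                     f, rater_set, cells$n_gray_levels[ci], cells$resampling[ci]),
             call. = FALSE)
      }
      res <- icc_consistency(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, family = man$family[man$name == f],
        n_gray_levels = cells$n_gray_levels[ci],
        resampling = cells$resampling[ci], rater_set = rater_set,
        icc = res$icc, category = res$category, degenerate = res$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  per_feature <- do.call(rbind, rows)
  fractions <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    sub <- per_feature[per_feature$n_gray_levels == cells$n_gray_levels[ci] &
                       per_feature$resampling == cells$resampling[ci], ]
    ok <- !sub$degenerate
    data.frame(n_gray_levels = cells$n_gray_levels[ci],
               resampling = cells$resampling[ci], rater_set = rater_set,
               n_features = nrow(sub), n_degenerate = sum(!ok),
               frac_poor = mean(sub$category[ok] == "poor"),
               frac_moderate = mean(sub$category[ok] == "moderate"),
               frac_good_to_excellent = mean(sub$category[ok] == "good_to_excellent"),
               stringsAsFactors = FALSE)
  }))
  fam_means <- stats::aggregate(icc ~ family + n_gray_levels + resampling,
                                data = per_feature[!per_feature$degenerate, ],
                                FUN = mean)
  fam_means$rater_set <- rater_set
  structure(list(per_feature = per_feature, fractions = fractions,
                 family_means = fam_means),
            class = "icc_report")
}
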
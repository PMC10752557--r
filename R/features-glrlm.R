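## Runs of equal gray level along one direction family. Out-of-mask pixels
## (NA) break runs: rle() treats each NA as its own run, which we drop.
glrlm_runs <- function(g, direction) {
  lines <- switch(direction,
                  horizontal = split(g, row(g)),
                  vertical = split(g, col(g)),
                  diag_down = split(g, row(g) - col(g)),
                  diag_up = split(g, row(g) + col(g)))
  runs <- lapply(lines, function(v) {
    r <- rle(as.vector(v))
    ok <- !is.na(r$values)
    cbind(level = r$values[ok], length = r$lengths[ok])
  })
  do.call(rbind, runs)
}

glrlm_matrix <- function(g, direction, levels, max_len) {
  runs <- glrlm_runs(g, direction)
  L <- length(levels)
  if (is.null(runs) || nrow(runs) == 0) return(matrix(0, L, max_len))
  idx <- (runs[, "length"] - 1L) * L + match(runs[, "level"], levels)
  matrix(tabulate(idx, nbins = L * max_len), L, max_len)
}

glrlm_features_one <- function(P, lv, Np) {
  lens <- seq_len(ncol(P))
  Nr <- sum(P)
  pg <- rowSums(P)
  pr <- colSums(P)
  pn <- P / Nr
  mu_g <- sum(rowSums(pn) * lv)
  mu_r <- sum(colSums(pn) * lens)
  c(GrayLevelNonUniformity = sum(pg^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nr^2,
    GrayLevelVariance = sum(rowSums(pn) * (lv - mu_g)^2),
    HighGrayLevelRunEmphasis = sum(pg * lv^2) / Nr,
    LongRunEmphasis = sum(pr * lens^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * outer(lv^2, lens^2)) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * outer(1 / lv^2, lens^2)) / Nr,
    LowGrayLevelRunEmphasis = sum(pg / lv^2) / Nr,
    RunEntropy = -sum(pn[pn > 0] * log2(pn[pn > 0])),
    RunLengthNonUniformity = sum(pr^2) / Nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / Nr^2,
    RunPercentage = Nr / Np,
    RunVariance = sum(colSums(pn) * (lens - mu_r)^2),
    ShortRunEmphasis = sum(pr / lens^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * outer(lv^2, 1 / lens^2)) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P * outer(1 / lv^2, 1 / lens^2)) / Nr)
}

#' Gray-level run-length matrix features (16)
#'
#' Runs of identical gray level along the four 2D directions, broken by the
#' mask boundary; one matrix per direction, features averaged over
#' directions. Run percentage is relative to the in-mask pixel count.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (`glrlm.*`).
#' @export
glrlm_features <- function(discretized_roi_grid, mask = NULL) {
  g <- as_roi_grid(discretized_roi_grid, mask)
  lv <- sort(unique(g[!is.na(g)]))
  Np <- sum(!is.na(g))
  max_len <- max(dim(g))
  dirs <- c("horizontal", "vertical", "diag_down", "diag_up")
  per_dir <- lapply(dirs, function(d) {
    glrlm_features_one(glrlm_matrix(g, d, lv, max_len), lv, Np)
  })
  out <- Reduce(`+`, per_dir) / length(per_dir)
  names(out) <- paste0("glrlm.", names(out))
  out
}
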
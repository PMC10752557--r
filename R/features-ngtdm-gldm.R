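## Shift a matrix by (dr, dc), padding with NA.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  rs <- seq.int(max(1L, 1L + dr), min(nr, nr + dr))
  cs <- seq.int(max(1L, 1L + dc), min(nc, nc + dc))
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Neighboring gray-tone difference matrix features (5)
#'
#' For every in-mask pixel with at least one in-mask 8-neighbor, the
#' absolute difference between its level and the mean level of its in-mask
#' neighbors is accumulated per gray level. Yields coarseness, contrast,
#' busyness, complexity, and strength. Degenerate rules: a flat ROI has all
#' differences zero, and coarseness returns the cap 1e6 when its denominator
#' vanishes; contrast is 0 for a single-level ROI; busyness and strength are
#' 0 when their denominators vanish.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features (`ngtdm.*`).
#' @export
ngtdm_features <- function(discretized_roi_grid, mask = NULL) {
  g <- as_roi_grid(discretized_roi_grid, mask)
  inmask <- !is.na(g)
  nb_sum <- matrix(0, nrow(g), ncol(g))
  nb_cnt <- matrix(0L, nrow(g), ncol(g))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- shift_mat(g, dr, dc)
    ok <- !is.na(s)
    nb_sum[ok] <- nb_sum[ok] + s[ok]
    nb_cnt <- nb_cnt + ok
  }
  valid <- inmask & nb_cnt > 0
  if (!any(valid)) stop("no pixel has an in-mask neighbor for NGTDM", call. = FALSE)
  A <- nb_sum[valid] / nb_cnt[valid]
  v <- g[valid]
  lv <- sort(unique(v))
  n_i <- as.vector(table(factor(v, levels = lv)))
  s_i <- as.vector(tapply(abs(v - A), factor(v, levels = lv), sum))
  s_i[is.na(s_i)] <- 0
  Nvp <- length(v)
  p_i <- n_i / Nvp
  Ngp <- length(lv)
  ii <- matrix(lv, Ngp, Ngp); jj <- t(ii)
  pi_m <- matrix(p_i, Ngp, Ngp); pj_m <- t(pi_m)
  si_m <- matrix(s_i, Ngp, Ngp); sj_m <- t(si_m)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den == 0) 1e6 else 1 / coarse_den
  contrast <- if (Ngp == 1) 0 else
    sum(pi_m * pj_m * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  busy_den <- sum(abs(ii * pi_m - jj * pj_m))
  busyness <- if (busy_den == 0) 0 else coarse_den / busy_den
  complexity <- sum(abs(ii - jj) * (pi_m * si_m + pj_m * sj_m) / (pi_m + pj_m)) / Nvp
  strength <- if (sum(s_i) == 0) 0 else
    sum((pi_m + pj_m) * (ii - jj)^2) / sum(s_i)
  c(ngtdm.Busyness = busyness, ngtdm.Coarseness = coarseness,
    ngtdm.Complexity = complexity, ngtdm.Contrast = contrast,
    ngtdm.Strength = strength)
}

#' Gray-level dependence matrix features (14)
#'
#' The dependence of a pixel is the number of its distance-1 axial neighbors
#' (4-neighborhood) that are in-mask and share its level exactly (similarity
#' tolerance 0), so an interior pixel of a flat region has dependence 4 and
#' every checkerboard pixel has dependence 0. The matrix counts pixels by
#' (gray level, dependence); feature formulas use the dependence index
#' `j = dependence + 1` so the small-dependence emphases remain defined at
#' dependence 0.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features (`gldm.*`).
#' @export
gldm_features <- function(discretized_roi_grid, mask = NULL) {
  g <- as_roi_grid(discretized_roi_grid, mask)
  inmask <- !is.na(g)
  dep <- matrix(0L, nrow(g), ncol(g))
  for (off in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    s <- shift_mat(g, off[1], off[2])
    same <- !is.na(s) & !is.na(g) & s == g
    dep <- dep + same
  }
  v <- g[inmask]
  d <- dep[inmask]
  lv <- sort(unique(v))
  jv <- seq_len(max(d) + 1L)                 # dependence index = d + 1
  L <- length(lv)
  idx <- d * L + match(v, lv)
  P <- matrix(tabulate(idx, nbins = L * length(jv)), L, length(jv))
  Nz <- sum(P)
  pg <- rowSums(P)
  pd <- colSums(P)
  pn <- P / Nz
  mu_g <- sum(rowSums(pn) * lv)
  mu_d <- sum(colSums(pn) * jv)
  out <- c(DependenceEntropy = -sum(pn[pn > 0] * log2(pn[pn > 0])),
           DependenceNonUniformity = sum(pd^2) / Nz,
           DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
           DependenceVariance = sum(colSums(pn) * (jv - mu_d)^2),
           GrayLevelNonUniformity = sum(pg^2) / Nz,
           GrayLevelVariance = sum(rowSums(pn) * (lv - mu_g)^2),
           HighGrayLevelEmphasis = sum(pg * lv^2) / Nz,
           LargeDependenceEmphasis = sum(pd * jv^2) / Nz,
           LargeDependenceHighGrayLevelEmphasis = sum(P * outer(lv^2, jv^2)) / Nz,
           LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / lv^2, jv^2)) / Nz,
           LowGrayLevelEmphasis = sum(pg / lv^2) / Nz,
           SmallDependenceEmphasis = sum(pd / jv^2) / Nz,
           SmallDependenceHighGrayLevelEmphasis = sum(P * outer(lv^2, 1 / jv^2)) / Nz,
           SmallDependenceLowGrayLevelEmphasis = sum(P * outer(1 / lv^2, 1 / jv^2)) / Nz)
  names(out) <- paste0("gldm.", names(out))
  out
}
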
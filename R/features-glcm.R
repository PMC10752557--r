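## 2D texture direction offsets (row, col): 0, 45, 90, 135 degrees at
## Chebyshev distance 1. Symmetric matrices make the opposite offsets
## redundant.
texture_offsets <- function() list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

## Coerce (grid, mask) to an integer grid with NA outside the mask.
as_roi_grid <- function(grid, mask = NULL) {
  g <- grid
  storage.mode(g) <- "integer"
  if (!is.null(mask)) {
    stop_if_not_congruent(g, mask, "grid and mask")
    g[!mask] <- NA_integer_
  }
  if (!any(!is.na(g))) stop("ROI is empty", call. = FALSE)
  g
}

## One symmetric co-occurrence count matrix for a single direction.
glcm_direction <- function(g, off, levels) {
  nr <- nrow(g); nc <- ncol(g); L <- length(levels)
  dr <- off[1]; dc <- off[2]
  ra <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
  ca <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
  a <- g[ra, ca, drop = FALSE]
  b <- g[ra + dr, ca + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  ia <- match(a[ok], levels); ib <- match(b[ok], levels)
  P <- matrix(tabulate((ia - 1L) * L + ib, nbins = L * L), L, L, byrow = TRUE)
  P + t(P)
}

glcm_features_one <- function(P, levels, eps = 0) {
  keep <- rowSums(P) > 0
  P <- P[keep, keep, drop = FALSE]
  lv <- levels[keep]
  Ng <- length(lv)
  p <- P / sum(P)
  px <- rowSums(p)                        # = py by symmetry
  I <- matrix(lv, Ng, Ng)
  J <- t(I)
  mu <- sum(p * I)
  sig2 <- sum(p * (I - mu)^2)
  ps <- tapply(as.vector(p), as.vector(I + J), sum)
  ks <- as.numeric(names(ps))
  pd <- tapply(as.vector(p), as.vector(abs(I - J)), sum)
  kd <- as.numeric(names(pd))
  da <- sum(pd * kd)
  H <- -sum(p[p > 0] * log2(p[p > 0]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  pxy <- outer(px, px)
  m <- p > 0
  HXY1 <- -sum(p[m] * log2(pxy[m]))
  m2 <- pxy > 0
  HXY2 <- -sum(pxy[m2] * log2(pxy[m2]))
  imc1 <- if (HX == 0) 0 else (H - HXY1) / HX
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - H))))
  offdiag <- I != J
  corr <- if (sig2 == 0) 1 else (sum(p * I * J) - mu^2) / sig2
  mcc <- if (Ng < 2) 1 else {
    Q <- sweep(p, 1, px, "/") %*% t(sweep(p, 2, px, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(max(ev[2], 0), 1))
  }
  c(Autocorrelation = sum(p * I * J),
    ClusterProminence = sum(p * (I + J - 2 * mu)^4),
    ClusterShade = sum(p * (I + J - 2 * mu)^3),
    ClusterTendency = sum(p * (I + J - 2 * mu)^2),
    Contrast = sum(p * (I - J)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum(pd * (kd - da)^2),
    Id = sum(p / (1 + abs(I - J))),
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + (I - J)^2 / Ng^2)),
    Idn = sum(p / (1 + abs(I - J) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offdiag] / (I[offdiag] - J[offdiag])^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = H,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ps * ks),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sig2)
}

#' Gray-level co-occurrence matrix features (24)
#'
#' Symmetric GLCM at distance 1 over the four unique 2D directions; one
#' matrix per direction, features computed per direction and then averaged
#' over directions that contain at least one in-mask pixel pair. Pairs are
#' counted only when both pixels lie inside the mask. Gray-level weights are
#' the discretized bin values themselves; rows/columns for absent levels are
#' dropped, and `Ng` in the normalized inverse-difference features is the
#' number of levels present in that direction's matrix. Degenerate rules:
#' correlation and MCC are 1 for a single-level matrix.
#'
#' @param discretized_roi_grid Integer matrix of bin indices with `NA`
#'   outside the ROI (or any grid if `mask` is given).
#' @param mask Optional logical matrix selecting the ROI.
#' @return Named numeric vector of 24 features (`glcm.*`).
#' @export
glcm_features <- function(discretized_roi_grid, mask = NULL) {
  g <- as_roi_grid(discretized_roi_grid, mask)
  levels <- sort(unique(g[!is.na(g)]))
  per_dir <- lapply(texture_offsets(), function(off) {
    P <- glcm_direction(g, off, levels)
    if (sum(P) == 0) NULL else glcm_features_one(P, levels)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (length(per_dir) == 0L) {
    stop("no valid in-mask pixel pairs for GLCM", call. = FALSE)
  }
  out <- Reduce(`+`, per_dir) / length(per_dir)
  names(out) <- paste0("glcm.", names(out))
  out
}
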
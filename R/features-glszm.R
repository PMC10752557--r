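## Zone inventory: 8-connected components of equal gray level inside the
## mask. Edges only ever connect pixels of the same level, so one component
## run over the whole ROI yields all zones of all levels at once.
glszm_zones <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  inmask <- !is.na(g)
  id <- matrix(NA_integer_, nr, nc)
  id[inmask] <- seq_len(sum(inmask))
  edges <- lapply(list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)), function(off) {
    dr <- off[1]; dc <- off[2]
    ra <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    ca <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    a <- g[ra, ca, drop = FALSE]
    b <- g[ra + dr, ca + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    cbind(id[ra, ca, drop = FALSE][ok],
          id[ra + dr, ca + dc, drop = FALSE][ok])
  })
  edges <- do.call(rbind, edges)
  n <- sum(inmask)
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) gr <- igraph::add_edges(gr, t(edges))
  memb <- igraph::components(gr)$membership
  vals <- g[inmask][order(id[inmask])]
  data.frame(level = as.vector(tapply(vals, memb, function(v) v[1])),
             size = as.vector(tapply(vals, memb, length)))
}

glszm_features_one <- function(zones, Np) {
  lv <- sort(unique(zones$level))
  sz <- sort(unique(zones$size))
  L <- length(lv)
  idx <- (match(zones$size, sz) - 1L) * L + match(zones$level, lv)
  P <- matrix(tabulate(idx, nbins = L * length(sz)), L, length(sz))
  Nz <- sum(P)
  pg <- rowSums(P)
  ps <- colSums(P)
  pn <- P / Nz
  mu_g <- sum(rowSums(pn) * lv)
  mu_s <- sum(colSums(pn) * sz)
  c(GrayLevelNonUniformity = sum(pg^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / Nz^2,
    GrayLevelVariance = sum(rowSums(pn) * (lv - mu_g)^2),
    HighGrayLevelZoneEmphasis = sum(pg * lv^2) / Nz,
    LargeAreaEmphasis = sum(ps * sz^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * outer(lv^2, sz^2)) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * outer(1 / lv^2, sz^2)) / Nz,
    LowGrayLevelZoneEmphasis = sum(pg / lv^2) / Nz,
    SizeZoneNonUniformity = sum(ps^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / Nz^2,
    SmallAreaEmphasis = sum(ps / sz^2) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * outer(lv^2, 1 / sz^2)) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(P * outer(1 / lv^2, 1 / sz^2)) / Nz,
    ZoneEntropy = -sum(pn[pn > 0] * log2(pn[pn > 0])),
    ZonePercentage = Nz / Np,
    ZoneVariance = sum(colSums(pn) * (sz - mu_s)^2))
}

#' Gray-level size-zone matrix features (16)
#'
#' Zones are 8-connected components of equal discretized level inside the
#' mask; a single (orientation-free) matrix of zone counts by gray level and
#' zone size.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (`glszm.*`).
#' @export
glszm_features <- function(discretized_roi_grid, mask = NULL) {
  g <- as_roi_grid(discretized_roi_grid, mask)
  zones <- glszm_zones(g)
  out <- glszm_features_one(zones, Np = sum(!is.na(g)))
  names(out) <- paste0("glszm.", names(out))
  out
}
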
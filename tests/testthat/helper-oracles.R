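## Independent brute-force oracles for the texture families: explicit loops
## over pixel pairs, runs, zones, and neighborhoods, plus loop-based feature
## formulas. Deliberately naive and separate from the package's vectorized
## implementations.

random_grid <- function(nr, nc, n_levels, p_out = 0.2) {
  g <- matrix(sample.int(n_levels, nr * nc, replace = TRUE), nr, nc)
  g[stats::runif(nr * nc) < p_out] <- NA_integer_
  if (all(is.na(g))) g[1, 1] <- 1L
  g
}

in_bounds <- function(g, r, c) r >= 1 && r <= nrow(g) && c >= 1 && c <= ncol(g)

## ---- GLCM ----

bf_glcm_dir <- function(g, off) {
  lv <- sort(unique(g[!is.na(g)]))
  L <- length(lv)
  P <- matrix(0, L, L)
  for (r in seq_len(nrow(g))) for (c in seq_len(ncol(g))) {
    if (is.na(g[r, c])) next
    for (s in c(1L, -1L)) {
      r2 <- r + s * off[1]; c2 <- c + s * off[2]
      if (in_bounds(g, r2, c2) && !is.na(g[r2, c2])) {
        i <- match(g[r, c], lv); j <- match(g[r2, c2], lv)
        P[i, j] <- P[i, j] + 1
      }
    }
  }
  list(P = P, levels = lv)
}

bf_glcm_features_one <- function(P, lv) {
  keep <- which(rowSums(P) > 0)
  P <- P[keep, keep, drop = FALSE]
  lv <- lv[keep]
  Ng <- length(lv)
  p <- P / sum(P)
  px <- numeric(Ng)
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) px[i] <- px[i] + p[i, j]
  mu <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) mu <- mu + p[i, j] * lv[i]
  out <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
           ClusterTendency = 0, Contrast = 0, Correlation = 0,
           DifferenceAverage = 0, DifferenceEntropy = 0,
           DifferenceVariance = 0, Id = 0, Idm = 0, Idmn = 0, Idn = 0,
           Imc1 = 0, Imc2 = 0, InverseVariance = 0, JointAverage = mu,
           JointEnergy = 0, JointEntropy = 0, MCC = 0,
           MaximumProbability = max(p), SumAverage = 0, SumEntropy = 0,
           SumSquares = 0)
  sig2 <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    sig2 <- sig2 + p[i, j] * (lv[i] - mu)^2
  }
  ## k-indexed marginals
  sums <- sort(unique(as.vector(outer(lv, lv, `+`))))
  diffs <- sort(unique(as.vector(abs(outer(lv, lv, `-`)))))
  ps <- setNames(numeric(length(sums)), sums)
  pd <- setNames(numeric(length(diffs)), diffs)
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    ps[as.character(lv[i] + lv[j])] <- ps[as.character(lv[i] + lv[j])] + p[i, j]
    pd[as.character(abs(lv[i] - lv[j]))] <-
      pd[as.character(abs(lv[i] - lv[j]))] + p[i, j]
  }
  da <- sum(pd * diffs)
  H <- 0; HX <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in seq_len(Ng)) if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    if (p[i, j] > 0) {
      H <- H - p[i, j] * log2(p[i, j])
      HXY1 <- HXY1 - p[i, j] * log2(px[i] * px[j])
    }
    if (px[i] * px[j] > 0) {
      HXY2 <- HXY2 - px[i] * px[j] * log2(px[i] * px[j])
    }
    out["Autocorrelation"] <- out["Autocorrelation"] + p[i, j] * lv[i] * lv[j]
    out["ClusterProminence"] <- out["ClusterProminence"] +
      p[i, j] * (lv[i] + lv[j] - 2 * mu)^4
    out["ClusterShade"] <- out["ClusterShade"] +
      p[i, j] * (lv[i] + lv[j] - 2 * mu)^3
    out["ClusterTendency"] <- out["ClusterTendency"] +
      p[i, j] * (lv[i] + lv[j] - 2 * mu)^2
    out["Contrast"] <- out["Contrast"] + p[i, j] * (lv[i] - lv[j])^2
    out["Id"] <- out["Id"] + p[i, j] / (1 + abs(lv[i] - lv[j]))
    out["Idm"] <- out["Idm"] + p[i, j] / (1 + (lv[i] - lv[j])^2)
    out["Idmn"] <- out["Idmn"] + p[i, j] / (1 + (lv[i] - lv[j])^2 / Ng^2)
    out["Idn"] <- out["Idn"] + p[i, j] / (1 + abs(lv[i] - lv[j]) / Ng)
    if (i != j) {
      out["InverseVariance"] <- out["InverseVariance"] +
        p[i, j] / (lv[i] - lv[j])^2
    }
    out["JointEnergy"] <- out["JointEnergy"] + p[i, j]^2
    out["SumSquares"] <- out["SumSquares"] + p[i, j] * (lv[i] - mu)^2
  }
  out["Correlation"] <- if (sig2 == 0) 1 else
    (out[["Autocorrelation"]] - mu^2) / sig2
  out["DifferenceAverage"] <- da
  out["DifferenceEntropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  out["DifferenceVariance"] <- sum(pd * (diffs - da)^2)
  out["JointEntropy"] <- H
  out["Imc1"] <- if (HX == 0) 0 else (H - HXY1) / HX
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (HXY2 - H))))
  out["SumAverage"] <- sum(ps * sums)
  out["SumEntropy"] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  out["MCC"] <- if (Ng < 2) 1 else {
    Q <- matrix(0, Ng, Ng)
    for (i in seq_len(Ng)) for (j in seq_len(Ng)) for (k in seq_len(Ng)) {
      Q[i, j] <- Q[i, j] + p[i, k] * p[j, k] / (px[i] * px[k])
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(max(ev[2], 0), 1))
  }
  out
}

bf_glcm_features <- function(g) {
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  per <- list()
  for (off in offs) {
    b <- bf_glcm_dir(g, off)
    if (sum(b$P) > 0) per[[length(per) + 1L]] <- bf_glcm_features_one(b$P, b$levels)
  }
  out <- Reduce(`+`, per) / length(per)
  names(out) <- paste0("glcm.", names(out))
  out
}

## ---- GLRLM ----

bf_glrlm_runs_dir <- function(g, off) {
  nr <- nrow(g); nc <- ncol(g)
  runs <- list()
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - off[1]; pc <- c - off[2]
    if (!in_bounds(g, pr, pc)) starts[[length(starts) + 1L]] <- c(r, c)
  }
  for (st in starts) {
    r <- st[1]; c <- st[2]
    cur <- NA; len <- 0L
    while (in_bounds(g, r, c)) {
      v <- g[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
        cur <- v; len <- 1L
      }
      r <- r + off[1]; c <- c + off[2]
    }
    if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
  }
  if (length(runs) == 0) return(NULL)
  m <- do.call(rbind, runs)
  colnames(m) <- c("level", "length")
  m
}

bf_glrlm_features_one <- function(runs, lv, Np) {
  Nr <- nrow(runs)
  out <- c(GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
           GrayLevelVariance = 0, HighGrayLevelRunEmphasis = 0,
           LongRunEmphasis = 0, LongRunHighGrayLevelEmphasis = 0,
           LongRunLowGrayLevelEmphasis = 0, LowGrayLevelRunEmphasis = 0,
           RunEntropy = 0, RunLengthNonUniformity = 0,
           RunLengthNonUniformityNormalized = 0, RunPercentage = Nr / Np,
           RunVariance = 0, ShortRunEmphasis = 0,
           ShortRunHighGrayLevelEmphasis = 0, ShortRunLowGrayLevelEmphasis = 0)
  for (i in lv) {
    ni <- sum(runs[, "level"] == i)
    out["GrayLevelNonUniformity"] <- out["GrayLevelNonUniformity"] + ni^2 / Nr
    out["GrayLevelNonUniformityNormalized"] <-
      out["GrayLevelNonUniformityNormalized"] + ni^2 / Nr^2
    out["HighGrayLevelRunEmphasis"] <-
      out["HighGrayLevelRunEmphasis"] + ni * i^2 / Nr
    out["LowGrayLevelRunEmphasis"] <-
      out["LowGrayLevelRunEmphasis"] + ni / i^2 / Nr
  }
  for (l in sort(unique(runs[, "length"]))) {
    nl <- sum(runs[, "length"] == l)
    out["RunLengthNonUniformity"] <- out["RunLengthNonUniformity"] + nl^2 / Nr
    out["RunLengthNonUniformityNormalized"] <-
      out["RunLengthNonUniformityNormalized"] + nl^2 / Nr^2
    out["LongRunEmphasis"] <- out["LongRunEmphasis"] + nl * l^2 / Nr
    out["ShortRunEmphasis"] <- out["ShortRunEmphasis"] + nl / l^2 / Nr
  }
  mu_g <- 0; mu_r <- 0
  for (k in seq_len(nrow(runs))) {
    mu_g <- mu_g + runs[k, "level"] / Nr
    mu_r <- mu_r + runs[k, "length"] / Nr
    i <- runs[k, "level"]; l <- runs[k, "length"]
    out["LongRunHighGrayLevelEmphasis"] <-
      out["LongRunHighGrayLevelEmphasis"] + i^2 * l^2 / Nr
    out["LongRunLowGrayLevelEmphasis"] <-
      out["LongRunLowGrayLevelEmphasis"] + l^2 / i^2 / Nr
    out["ShortRunHighGrayLevelEmphasis"] <-
      out["ShortRunHighGrayLevelEmphasis"] + i^2 / l^2 / Nr
    out["ShortRunLowGrayLevelEmphasis"] <-
      out["ShortRunLowGrayLevelEmphasis"] + 1 / (i^2 * l^2) / Nr
  }
  for (k in seq_len(nrow(runs))) {
    out["GrayLevelVariance"] <- out["GrayLevelVariance"] +
      (runs[k, "level"] - mu_g)^2 / Nr
    out["RunVariance"] <- out["RunVariance"] +
      (runs[k, "length"] - mu_r)^2 / Nr
  }
  cells <- table(paste(runs[, "level"], runs[, "length"]))
  pn <- as.numeric(cells) / Nr
  out["RunEntropy"] <- -sum(pn * log2(pn))
  out
}

bf_glrlm_features <- function(g) {
  lv <- sort(unique(g[!is.na(g)]))
  Np <- sum(!is.na(g))
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  per <- lapply(offs, function(off) {
    runs <- bf_glrlm_runs_dir(g, off)
    bf_glrlm_features_one(runs, lv, Np)
  })
  out <- Reduce(`+`, per) / length(per)
  names(out) <- paste0("glrlm.", names(out))
  out
}

## ---- GLSZM (flood fill) ----

bf_glszm_zones <- function(g) {
  seen <- matrix(FALSE, nrow(g), ncol(g))
  zones <- list()
  for (r0 in seq_len(nrow(g))) for (c0 in seq_len(ncol(g))) {
    if (is.na(g[r0, c0]) || seen[r0, c0]) next
    lvl <- g[r0, c0]
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      pos <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- pos[1] + dr; c <- pos[2] + dc
        if (in_bounds(g, r, c) && !seen[r, c] && !is.na(g[r, c]) &&
            g[r, c] == lvl) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = lvl, size = size)
  }
  as.data.frame(do.call(rbind, zones))
}

bf_glszm_features <- function(g) {
  zones <- bf_glszm_zones(g)
  Np <- sum(!is.na(g))
  Nz <- nrow(zones)
  lv <- sort(unique(zones$level))
  sz <- sort(unique(zones$size))
  out <- c(GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
           GrayLevelVariance = 0, HighGrayLevelZoneEmphasis = 0,
           LargeAreaEmphasis = 0, LargeAreaHighGrayLevelEmphasis = 0,
           LargeAreaLowGrayLevelEmphasis = 0, LowGrayLevelZoneEmphasis = 0,
           SizeZoneNonUniformity = 0, SizeZoneNonUniformityNormalized = 0,
           SmallAreaEmphasis = 0, SmallAreaHighGrayLevelEmphasis = 0,
           SmallAreaLowGrayLevelEmphasis = 0, ZoneEntropy = 0,
           ZonePercentage = Nz / Np, ZoneVariance = 0)
  for (i in lv) {
    ni <- sum(zones$level == i)
    out["GrayLevelNonUniformity"] <- out["GrayLevelNonUniformity"] + ni^2 / Nz
    out["GrayLevelNonUniformityNormalized"] <-
      out["GrayLevelNonUniformityNormalized"] + ni^2 / Nz^2
    out["HighGrayLevelZoneEmphasis"] <-
      out["HighGrayLevelZoneEmphasis"] + ni * i^2 / Nz
    out["LowGrayLevelZoneEmphasis"] <-
      out["LowGrayLevelZoneEmphasis"] + ni / i^2 / Nz
  }
  for (s in sz) {
    ns <- sum(zones$size == s)
    out["SizeZoneNonUniformity"] <- out["SizeZoneNonUniformity"] + ns^2 / Nz
    out["SizeZoneNonUniformityNormalized"] <-
      out["SizeZoneNonUniformityNormalized"] + ns^2 / Nz^2
    out["LargeAreaEmphasis"] <- out["LargeAreaEmphasis"] + ns * s^2 / Nz
    out["SmallAreaEmphasis"] <- out["SmallAreaEmphasis"] + ns / s^2 / Nz
  }
  mu_g <- mean(zones$level)
  mu_s <- mean(zones$size)
  for (k in seq_len(Nz)) {
    i <- zones$level[k]; s <- zones$size[k]
    out["GrayLevelVariance"] <- out["GrayLevelVariance"] + (i - mu_g)^2 / Nz
    out["ZoneVariance"] <- out["ZoneVariance"] + (s - mu_s)^2 / Nz
    out["LargeAreaHighGrayLevelEmphasis"] <-
      out["LargeAreaHighGrayLevelEmphasis"] + i^2 * s^2 / Nz
    out["LargeAreaLowGrayLevelEmphasis"] <-
      out["LargeAreaLowGrayLevelEmphasis"] + s^2 / i^2 / Nz
    out["SmallAreaHighGrayLevelEmphasis"] <-
      out["SmallAreaHighGrayLevelEmphasis"] + i^2 / s^2 / Nz
    out["SmallAreaLowGrayLevelEmphasis"] <-
      out["SmallAreaLowGrayLevelEmphasis"] + 1 / (i^2 * s^2) / Nz
  }
  cells <- table(paste(zones$level, zones$size))
  pn <- as.numeric(cells) / Nz
  out["ZoneEntropy"] <- -sum(pn * log2(pn))
  names(out) <- paste0("glszm.", names(out))
  out
}

## ---- NGTDM ----

bf_ngtdm_features <- function(g) {
  lv <- sort(unique(g[!is.na(g)]))
  n_i <- setNames(numeric(length(lv)), lv)
  s_i <- setNames(numeric(length(lv)), lv)
  Nvp <- 0L
  for (r in seq_len(nrow(g))) for (c in seq_len(ncol(g))) {
    if (is.na(g[r, c])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (in_bounds(g, r + dr, c + dc) && !is.na(g[r + dr, c + dc])) {
        nb <- c(nb, g[r + dr, c + dc])
      }
    }
    if (length(nb) == 0) next
    Nvp <- Nvp + 1L
    key <- as.character(g[r, c])
    n_i[key] <- n_i[key] + 1
    s_i[key] <- s_i[key] + abs(g[r, c] - mean(nb))
  }
  keep <- n_i > 0
  lv <- lv[keep]; n_i <- n_i[keep]; s_i <- s_i[keep]
  p_i <- n_i / Nvp
  Ngp <- length(lv)
  den <- sum(p_i * s_i)
  coarseness <- if (den == 0) 1e6 else 1 / den
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (a in seq_len(Ngp)) for (b in seq_len(Ngp)) {
    contrast <- contrast + p_i[a] * p_i[b] * (lv[a] - lv[b])^2
    busy_den <- busy_den + abs(lv[a] * p_i[a] - lv[b] * p_i[b])
    complexity <- complexity +
      abs(lv[a] - lv[b]) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    strength <- strength + (p_i[a] + p_i[b]) * (lv[a] - lv[b])^2
  }
  contrast <- if (Ngp == 1) 0 else contrast / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  c(ngtdm.Busyness = if (busy_den == 0) 0 else unname(den / busy_den),
    ngtdm.Coarseness = unname(coarseness),
    ngtdm.Complexity = unname(complexity / Nvp),
    ngtdm.Contrast = unname(contrast),
    ngtdm.Strength = if (sum(s_i) == 0) 0 else unname(strength / sum(s_i)))
}

## ---- GLDM ----

bf_gldm_features <- function(g) {
  lv <- sort(unique(g[!is.na(g)]))
  recs <- list()
  for (r in seq_len(nrow(g))) for (c in seq_len(ncol(g))) {
    if (is.na(g[r, c])) next
    d <- 0L
    for (off in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (in_bounds(g, r2, c2) && !is.na(g[r2, c2]) && g[r2, c2] == g[r, c]) {
        d <- d + 1L
      }
    }
    recs[[length(recs) + 1L]] <- c(level = g[r, c], j = d + 1L)
  }
  recs <- as.data.frame(do.call(rbind, recs))
  Nz <- nrow(recs)
  jv <- sort(unique(recs$j))
  out <- c(DependenceEntropy = 0, DependenceNonUniformity = 0,
           DependenceNonUniformityNormalized = 0, DependenceVariance = 0,
           GrayLevelNonUniformity = 0, GrayLevelVariance = 0,
           HighGrayLevelEmphasis = 0, LargeDependenceEmphasis = 0,
           LargeDependenceHighGrayLevelEmphasis = 0,
           LargeDependenceLowGrayLevelEmphasis = 0, LowGrayLevelEmphasis = 0,
           SmallDependenceEmphasis = 0,
           SmallDependenceHighGrayLevelEmphasis = 0,
           SmallDependenceLowGrayLevelEmphasis = 0)
  for (i in lv) {
    ni <- sum(recs$level == i)
    out["GrayLevelNonUniformity"] <- out["GrayLevelNonUniformity"] + ni^2 / Nz
    out["HighGrayLevelEmphasis"] <- out["HighGrayLevelEmphasis"] + ni * i^2 / Nz
    out["LowGrayLevelEmphasis"] <- out["LowGrayLevelEmphasis"] + ni / i^2 / Nz
  }
  for (j in jv) {
    nj <- sum(recs$j == j)
    out["DependenceNonUniformity"] <- out["DependenceNonUniformity"] + nj^2 / Nz
    out["DependenceNonUniformityNormalized"] <-
      out["DependenceNonUniformityNormalized"] + nj^2 / Nz^2
    out["LargeDependenceEmphasis"] <- out["LargeDependenceEmphasis"] + nj * j^2 / Nz
    out["SmallDependenceEmphasis"] <- out["SmallDependenceEmphasis"] + nj / j^2 / Nz
  }
  mu_g <- mean(recs$level)
  mu_j <- mean(recs$j)
  for (k in seq_len(Nz)) {
    i <- recs$level[k]; j <- recs$j[k]
    out["GrayLevelVariance"] <- out["GrayLevelVariance"] + (i - mu_g)^2 / Nz
    out["DependenceVariance"] <- out["DependenceVariance"] + (j - mu_j)^2 / Nz
    out["LargeDependenceHighGrayLevelEmphasis"] <-
      out["LargeDependenceHighGrayLevelEmphasis"] + i^2 * j^2 / Nz
    out["LargeDependenceLowGrayLevelEmphasis"] <-
      out["LargeDependenceLowGrayLevelEmphasis"] + j^2 / i^2 / Nz
    out["SmallDependenceHighGrayLevelEmphasis"] <-
      out["SmallDependenceHighGrayLevelEmphasis"] + i^2 / j^2 / Nz
    out["SmallDependenceLowGrayLevelEmphasis"] <-
      out["SmallDependenceLowGrayLevelEmphasis"] + 1 / (i^2 * j^2) / Nz
  }
  cells <- table(paste(recs$level, recs$j))
  pn <- as.numeric(cells) / Nz
  out["DependenceEntropy"] <- -sum(pn * log2(pn))
  names(out) <- paste0("gldm.", names(out))
  out
}

bf_all_texture_features <- function(g) {
  c(bf_glcm_features(g), bf_glrlm_features(g), bf_glszm_features(g),
    bf_ngtdm_features(g), bf_gldm_features(g))
}

pkg_all_texture_features <- function(g) {
  c(glcm_features(g), glrlm_features(g), glszm_features(g),
    ngtdm_features(g), gldm_features(g))
}

## ---- ICC oracle: explicit sums of squares, plus lm/anova mean squares ----

bf_icc_consistency <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- 0
  for (i in seq_len(n)) msr <- msr + k * (mean(m[i, ]) - grand)^2
  msr <- msr / (n - 1)
  sse <- 0
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - rm_[i] - cm_[j] + grand)^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

anova_icc_consistency <- function(m) {
  df <- data.frame(value = as.vector(m),
                   unit = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- stats::anova(stats::lm(value ~ unit + rater, data = df))
  msr <- tab["unit", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

## ---- AUC oracle: explicit concordant-pair count ----

bf_auc <- function(values, labels) {
  pos <- values[labels]
  neg <- values[!labels]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}
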
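# Texture matrix families on the discretized ROI. All matrices are built
# in 3D at distance 1. GLCM and GLRLM are computed per direction over the
# 13 unique 3D angles and direction-averaged; GLSZM, NGTDM and GLDM use the
# full 26-neighbourhood and yield one matrix each.

# Per-direction symmetric normalized co-occurrence matrices.
glcm_matrices <- function(d) {
  dirs <- unique_directions_3d()
  Ng <- d$Ng
  mask_num <- d$mask * 1
  out <- list()
  for (k in seq_len(nrow(dirs))) {
    sm <- shift_array_3d(mask_num, dirs[k, 1], dirs[k, 2], dirs[k, 3])
    sg <- shift_array_3d(d$gray, dirs[k, 1], dirs[k, 2], dirs[k, 3])
    valid <- d$mask & (sm == 1)
    if (!any(valid)) next
    i <- d$gray[valid]; j <- sg[valid]
    P <- matrix(tabulate((j - 1L) * Ng + i, Ng * Ng), Ng, Ng)
    P <- P + t(P)
    out[[length(out) + 1]] <- P / sum(P)
  }
  if (length(out) == 0) {
    # single-voxel ROI: degenerate single-entry matrix
    P <- matrix(0, Ng, Ng)
    P[d$gray[d$mask][1], d$gray[d$mask][1]] <- 1
    out <- list(P)
  }
  out
}

glcm_features_one <- function(p, Ng) {
  lv <- seq_len(Ng)
  I <- matrix(lv, Ng, Ng)
  J <- t(I)
  px <- rowSums(p)
  mu <- sum(I * p)
  sig2 <- sum((I - mu)^2 * p)
  sig <- sqrt(sig2)
  delta <- abs(I - J)
  pos <- p > 0
  # difference and sum distributions, accumulated by |i-j| and i+j
  pd <- numeric(Ng)
  pd_acc <- rowsum(as.numeric(p), as.integer(delta))
  pd[as.integer(rownames(pd_acc)) + 1] <- pd_acc
  ps <- numeric(2 * Ng - 1)
  ps_acc <- rowsum(as.numeric(p), as.integer(I + J))
  ps[as.integer(rownames(ps_acc)) - 1] <- ps_acc
  kd <- 0:(Ng - 1)
  ks <- 2:(2 * Ng)
  da <- sum(kd * pd)
  hxy <- -sum(p[pos] * log2(p[pos]))
  pxpy <- outer(px, px)
  ok <- pos & pxpy > 0
  hxy1 <- -sum(p[ok] * log2(pxpy[ok]))
  okm <- pxpy > 0
  hxy2 <- -sum(pxpy[okm] * log2(pxpy[okm]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0  # symmetric p => HX == HY
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  correlation <- if (sig2 > 1e-12) (sum(I * J * p) - mu^2) / sig2 else 1
  # MCC via the symmetric similarity transform of Q
  present <- which(px > 0)
  mcc <- if (length(present) < 2) {
    1
  } else {
    pp <- p[present, present, drop = FALSE]
    pxp <- px[present]
    # Q(i,j) = sum_k p_ik p_jk / (px_i py_k) is similar to the symmetric
    # M = D^-1/2 (A A^T) D^-1/2 with A = p / sqrt(py_k), D = diag(px),
    # so its eigenvalues are real and cheap to obtain.
    A <- sweep(pp, 2, sqrt(pxp), `/`)
    M <- tcrossprod(A) / sqrt(outer(pxp, pxp))
    M <- (M + t(M)) / 2
    evs <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    sqrt(pmax(evs[2], 0))
  }
  c(
    Autocorrelation = sum(I * J * p),
    ClusterProminence = sum((I + J - 2 * mu)^4 * p),
    ClusterShade = sum((I + J - 2 * mu)^3 * p),
    ClusterTendency = sum((I + J - 2 * mu)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = correlation,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(p / (1 + delta)),
    Idm = sum(p / (1 + delta^2)),
    Idmn = sum(p / (1 + delta^2 / Ng^2)),
    Idn = sum(p / (1 + delta / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[delta > 0] / delta[delta > 0]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sig2
  )
}

#' Gray-level co-occurrence features (24), direction-averaged
#'
#' Symmetric distance-1 co-occurrence matrices over the 13 unique 3D
#' directions, each normalized, with features averaged over directions.
#'
#' @param d A `discretized_roi` from [discretize()].
#' @param config A [radiomics_config()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(d, config = radiomics_config()) {
  mats <- glcm_matrices(d)
  feats <- vapply(mats, glcm_features_one, numeric(24), Ng = d$Ng)
  rowMeans(feats)
}

# Runs of equal gray level along one direction; returns (level, length)
# pairs for all maximal runs.
runs_one_direction <- function(d, dir) {
  idx <- which(d$mask)
  co <- arrayInd(idx, dim(d$mask))
  g <- d$gray[idx]
  t_pos <- co[, 1] * dir[1] + co[, 2] * dir[2] + co[, 3] * dir[3]
  k1 <- co[, 1] * dir[2] - co[, 2] * dir[1]
  k2 <- co[, 1] * dir[3] - co[, 3] * dir[1]
  k3 <- co[, 2] * dir[3] - co[, 3] * dir[2]
  key <- ((k1 + 500) * 1001 + (k2 + 500)) * 1001 + (k3 + 500)
  s2 <- sum(dir^2)
  ord <- order(key, t_pos)
  keyo <- key[ord]; to <- t_pos[ord]; go <- g[ord]
  n <- length(ord)
  if (n == 1) return(cbind(level = go, length = 1))
  brk <- c(TRUE, keyo[-1] != keyo[-n] | (to[-1] - to[-n]) != s2 |
             go[-1] != go[-n])
  run_id <- cumsum(brk)
  len <- tabulate(run_id)
  lev <- go[brk]
  cbind(level = lev, length = len)
}

glrlm_features_one <- function(runs, Ng, Np) {
  i <- runs[, 1]; r <- runs[, 2]
  Nr <- nrow(runs)
  pr <- 1 / Nr
  gl_sum <- tapply(rep(1, Nr), factor(i, levels = seq_len(Ng)), sum,
                   default = 0)
  rl_sum <- tapply(rep(1, Nr), factor(r, levels = seq_len(max(r))), sum,
                   default = 0)
  mu_i <- sum(i) / Nr
  mu_r <- sum(r) / Nr
  p_run <- rep(pr, Nr)
  c(
    GrayLevelNonUniformity = sum(gl_sum^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(gl_sum^2) / Nr^2,
    GrayLevelVariance = sum((i - mu_i)^2) / Nr,
    HighGrayLevelRunEmphasis = sum(i^2) / Nr,
    LongRunEmphasis = sum(r^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(i^2 * r^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(r^2 / i^2) / Nr,
    LowGrayLevelRunEmphasis = sum(1 / i^2) / Nr,
    RunEntropy = -sum((gl_rl <- table(i, r) / Nr)[gl_rl > 0] *
                        log2(gl_rl[gl_rl > 0])),
    RunLengthNonUniformity = sum(rl_sum^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rl_sum^2) / Nr^2,
    RunPercentage = Nr / Np,
    RunVariance = sum((r - mu_r)^2) / Nr,
    ShortRunEmphasis = sum(1 / r^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(i^2 / r^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(1 / (i^2 * r^2)) / Nr
  )
}

#' Gray-level run-length features (16), direction-averaged
#'
#' Maximal runs of identical gray level along each of the 13 unique 3D
#' directions; runs are broken by voxels outside the ROI.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(d, config = radiomics_config()) {
  dirs <- unique_directions_3d()
  Np <- sum(d$mask)
  feats <- vapply(seq_len(nrow(dirs)), function(k) {
    glrlm_features_one(runs_one_direction(d, dirs[k, ]), d$Ng, Np)
  }, numeric(16))
  rowMeans(feats)
}

# Zones: 26-connected components of constant gray level.
glszm_zones <- function(d) {
  levels_present <- sort(unique(d$gray[d$mask]))
  zones <- list()
  for (lvl in levels_present) {
    cc <- label_components_3d(d$gray == lvl & d$mask)
    if (cc$n == 0) next
    sizes <- tabulate(cc$labels[cc$labels > 0], cc$n)
    zones[[length(zones) + 1]] <- cbind(level = lvl, size = sizes)
  }
  do.call(rbind, zones)
}

#' Gray-level size-zone features (16)
#'
#' Orientation-free: each 26-connected zone of constant gray level is
#' counted once with its size.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(d, config = radiomics_config()) {
  z <- glszm_zones(d)
  i <- z[, 1]; s <- z[, 2]
  Nz <- nrow(z)
  Np <- sum(d$mask)
  gl_sum <- tapply(rep(1, Nz), factor(i, levels = seq_len(d$Ng)), sum,
                   default = 0)
  sz_sum <- tapply(rep(1, Nz), factor(s, levels = seq_len(max(s))), sum,
                   default = 0)
  mu_i <- mean(i)
  mu_s <- mean(s)
  pzs <- table(i, s) / Nz
  c(
    GrayLevelNonUniformity = sum(gl_sum^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(gl_sum^2) / Nz^2,
    GrayLevelVariance = sum((i - mu_i)^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(i^2) / Nz,
    LargeAreaEmphasis = sum(s^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2) / Nz,
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / Nz,
    SizeZoneNonUniformity = sum(sz_sum^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(sz_sum^2) / Nz^2,
    SmallAreaEmphasis = sum(1 / s^2) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * s^2)) / Nz,
    ZoneEntropy = -sum(pzs[pzs > 0] * log2(pzs[pzs > 0])),
    ZonePercentage = Nz / Np,
    ZoneVariance = sum((s - mu_s)^2) / Nz
  )
}

# Neighbourhood averages over the 26-neighbourhood within the ROI.
ngtdm_components <- function(d) {
  off <- neighbour_offsets_3d()
  gray_num <- d$gray * (d$mask * 1)
  nb_sum <- array(0, dim(d$gray))
  nb_cnt <- array(0, dim(d$gray))
  for (k in seq_len(nrow(off))) {
    nb_sum <- nb_sum + shift_array_3d(gray_num, off$dx[k], off$dy[k], off$dz[k])
    nb_cnt <- nb_cnt + shift_array_3d(d$mask * 1, off$dx[k], off$dy[k], off$dz[k])
  }
  has_nb <- d$mask & nb_cnt > 0
  i_vals <- d$gray[has_nb]
  a_vals <- nb_sum[has_nb] / nb_cnt[has_nb]
  nvp <- sum(has_nb)
  lev <- seq_len(d$Ng)
  n_i <- tabulate(i_vals, d$Ng)
  s_i <- vapply(lev, function(l) sum(abs(l - a_vals[i_vals == l])), numeric(1))
  list(levels = lev, n = n_i, s = s_i, p = n_i / max(nvp, 1), nvp = nvp)
}

#' Neighbouring gray-tone difference features (5)
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' absolute differences between each voxel's gray level and the average of
#' its 26-neighbours inside the ROI.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(d, config = radiomics_config()) {
  cm <- ngtdm_components(d)
  pres <- which(cm$p > 0)
  p <- cm$p[pres]; s <- cm$s[pres]; iv <- cm$levels[pres]
  ngp <- length(pres)
  nvp <- max(cm$nvp, 1)
  ps_sum <- sum(p * s)
  coarseness <- if (ps_sum > 0) 1 / ps_sum else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p, p) * outer(iv, iv, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s) / nvp)
  } else {
    0
  }
  denom_b <- sum(abs(outer(iv * p, iv * p, `-`)))
  busyness <- if (denom_b > 0) ps_sum / denom_b else 0
  complexity <- if (ngp > 1) {
    sum(abs(outer(iv, iv, `-`)) *
          (outer(p * s, p * s, `+`)) / outer(p, p, `+`)) / nvp
  } else {
    0
  }
  strength <- if (sum(s) > 0) {
    sum(outer(p, p, `+`) * outer(iv, iv, `-`)^2) / sum(s)
  } else {
    0
  }
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

# Dependence counts: number of 26-neighbours inside the ROI whose gray
# level differs from the centre by at most alpha. Package convention:
# the stored count excludes the centre voxel (0 for an isolated voxel);
# feature formulas use dependence size j = count + 1.
gldm_counts <- function(d, alpha = 0) {
  off <- neighbour_offsets_3d()
  dep <- array(0L, dim(d$gray))
  for (k in seq_len(nrow(off))) {
    sm <- shift_array_3d(d$mask * 1, off$dx[k], off$dy[k], off$dz[k])
    sg <- shift_array_3d(d$gray, off$dx[k], off$dy[k], off$dz[k])
    dep <- dep + (d$mask & sm == 1 & abs(d$gray - sg) <= alpha)
  }
  cbind(level = d$gray[d$mask], count = dep[d$mask])
}

#' Gray-level dependence features (14)
#'
#' Distance-1, dependence threshold alpha = 0 by default. The dependence
#' count of a voxel is its number of 26-neighbours inside the ROI with an
#' identical (within alpha) gray level; feature formulas use the
#' dependence size j = count + 1.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(d, config = radiomics_config()) {
  dc <- gldm_counts(d, config$alpha)
  i <- dc[, 1]
  j <- dc[, 2] + 1
  Nz <- nrow(dc)
  gl_sum <- tapply(rep(1, Nz), factor(i, levels = seq_len(d$Ng)), sum,
                   default = 0)
  dp_sum <- tapply(rep(1, Nz), factor(j, levels = seq_len(max(j))), sum,
                   default = 0)
  mu_i <- mean(i)
  mu_j <- mean(j)
  pij <- table(i, j) / Nz
  c(
    DependenceEntropy = -sum(pij[pij > 0] * log2(pij[pij > 0])),
    DependenceNonUniformity = sum(dp_sum^2) / Nz,
    DependenceNonUniformityNormalized = sum(dp_sum^2) / Nz^2,
    DependenceVariance = sum((j - mu_j)^2) / Nz,
    GrayLevelNonUniformity = sum(gl_sum^2) / Nz,
    GrayLevelVariance = sum((i - mu_i)^2) / Nz,
    HighGrayLevelEmphasis = sum(i^2) / Nz,
    LargeDependenceEmphasis = sum(j^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(i^2 * j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(j^2 / i^2) / Nz,
    LowGrayLevelEmphasis = sum(1 / i^2) / Nz,
    SmallDependenceEmphasis = sum(1 / j^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(i^2 / j^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(1 / (i^2 * j^2)) / Nz
  )
}
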
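# Texture feature formulas operating on the co-occurrence / run-length /
# size-zone / dependence / gray-tone-difference matrices built in C++.
# GLCM and GLRLM features are computed per 3D direction (13 directions,
# distance 1, symmetric GLCM) and averaged over directions with observations.

EPS <- 2.2e-16

glcmFeaturesOneDir <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(NULL)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * p); muy <- sum(j * p)
  sx <- sqrt(sum((i - mux)^2 * p)); sy <- sqrt(sum((j - muy)^2 * p))
  kSum <- 2:(2 * ng); kDiff <- 0:(ng - 1)
  pSum <- vapply(kSum, function(k) sum(p[i + j == k]), 0)
  pDiff <- vapply(kDiff, function(k) sum(p[abs(i - j) == k]), 0)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2(pxy + EPS))
  hxy2 <- -sum(pxy * log2(pxy + EPS))
  da <- sum(kDiff * pDiff)
  mcc <- {
    if (ng < 2 || any(px == 0) || any(py == 0)) 1
    else {
      # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
      Q <- sweep(p, 1, px, "/") %*% t(sweep(p, 2, py, "/"))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, if (length(ev) > 1) ev[2] else ev[1]))
    }
  }
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sx * sy > 0)
      (sum(i * j * p) - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pDiff[pDiff > 0] * log2(pDiff[pDiff > 0])),
    DifferenceVariance = sum((kDiff - da)^2 * pDiff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumEntropy = -sum(pSum[pSum > 0] * log2(pSum[pSum > 0])))
}

glcmFeatures <- function(counts) {
  res <- lapply(seq_len(dim(counts)[3]), function(d)
    glcmFeaturesOneDir(matrix(counts[, , d], dim(counts)[1])))
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) stop("empty GLCM in every direction")
  Reduce(`+`, res) / length(res)
}

glrlmFeaturesOneDir <- function(P, np) {
  nr <- sum(P)
  if (nr == 0) return(NULL)
  p <- P / nr
  i <- row(P); j <- col(P)
  rg <- rowSums(P); rl <- colSums(P)
  muI <- sum(i * p); muJ <- sum(j * p)
  c(GrayLevelNonUniformity = sum(rg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rg^2) / nr^2,
    GrayLevelVariance = sum((i - muI)^2 * p),
    HighGrayLevelRunEmphasis = sum(i^2 * p),
    LongRunEmphasis = sum(j^2 * p),
    LongRunHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LongRunLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    RunLengthNonUniformity = sum(rl^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum((j - muJ)^2 * p),
    ShortRunEmphasis = sum(p / j^2),
    ShortRunHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2)))
}

glrlmFeatures <- function(counts, np) {
  res <- lapply(seq_len(dim(counts)[3]), function(d)
    glrlmFeaturesOneDir(matrix(counts[, , d], dim(counts)[1]), np))
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) stop("empty GLRLM in every direction")
  Reduce(`+`, res) / length(res)
}

glszmFeatures <- function(P, np) {
  nz <- sum(P)
  if (nz == 0) stop("empty GLSZM")
  p <- P / nz
  i <- row(P); j <- col(P)
  zg <- rowSums(P); zs <- colSums(P)
  muI <- sum(i * p); muJ <- sum(j * p)
  c(GrayLevelNonUniformity = sum(zg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(zg^2) / nz^2,
    GrayLevelVariance = sum((i - muI)^2 * p),
    HighGrayLevelZoneEmphasis = sum(i^2 * p),
    LargeAreaEmphasis = sum(j^2 * p),
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LargeAreaLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    SizeZoneNonUniformity = sum(zs^2) / nz,
    SizeZoneNonUniformityNormalized = sum(zs^2) / nz^2,
    SmallAreaEmphasis = sum(p / j^2),
    SmallAreaHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    ZonePercentage = nz / np,
    ZoneVariance = sum((j - muJ)^2 * p))
}

# Dependence j = 1 + number of 26-neighbours within alpha of the centre
# (the centre voxel itself counts, so j >= 1).
gldmFeatures <- function(P) {
  # P is ng x 27 with column c holding dependence c-1; j = c = dep + 1
  nd <- sum(P)
  if (nd == 0) stop("empty GLDM")
  p <- P / nd
  i <- row(P); j <- col(P)  # col c holds dependence c-1, so j = c = dep + 1
  dg <- rowSums(P); dd <- colSums(P)
  muI <- sum(i * p); muJ <- sum(j * p)
  c(DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    DependenceNonUniformity = sum(dd^2) / nd,
    DependenceNonUniformityNormalized = sum(dd^2) / nd^2,
    DependenceVariance = sum((j - muJ)^2 * p),
    GrayLevelNonUniformity = sum(dg^2) / nd,
    GrayLevelVariance = sum((i - muI)^2 * p),
    HighGrayLevelEmphasis = sum(i^2 * p),
    LargeDependenceEmphasis = sum(j^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelEmphasis = sum(p / i^2),
    SmallDependenceEmphasis = sum(p / j^2),
    SmallDependenceHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)))
}

ngtdmFeatures <- function(s, n) {
  nvp <- sum(n)
  if (nvp == 0) stop("empty NGTDM")
  p <- n / nvp
  act <- which(n > 0)
  ngp <- length(act)
  i <- seq_along(n)
  sumPS <- sum(p * s)
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(act, act, function(a, b) (a - b)^2)) /
      (ngp * (ngp - 1)) * sum(s) / nvp
  } else 0
  busyness <- {
    den <- sum(abs(outer(act * p[act], act * p[act], "-")))
    if (den > 0) sumPS / den else 0
  }
  complexity <- if (ngp > 1) {
    acc <- 0
    for (a in act) for (b in act)
      acc <- acc + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    acc / nvp
  } else 0
  strength <- {
    num <- 0
    for (a in act) for (b in act)
      num <- num + (p[a] + p[b]) * (a - b)^2
    if (sum(s) > 0) num / sum(s) else 0
  }
  c(Busyness = busyness,
    Coarseness = if (sumPS > 0) 1 / sumPS else 1e6,
    Complexity = complexity,
    Contrast = contrast,
    Strength = strength)
}

# canonical per-family feature name lists (73 texture features in total)
textureFeatureNames <- function() {
  list(
    glcm = names(glcmFeaturesOneDir(matrix(c(2, 1, 1, 2), 2, 2))),
    glrlm = names(glrlmFeaturesOneDir(matrix(c(2, 1, 1, 2), 2, 2), 6)),
    glszm = names(glszmFeatures(matrix(c(2, 1, 1, 2), 2, 2), 6)),
    gldm = names(gldmFeatures(matrix(1, 2, 27))),
    ngtdm = names(ngtdmFeatures(c(1, 1), c(2, 2))))
}
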
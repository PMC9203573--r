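# 14 morphological descriptors computed from the voxelized mask. Volume and
# surface use the voxel-union representation (face counting); axis lengths
# come from the PCA of foreground voxel centres; diameters are maximum
# pairwise boundary distances (3D and within axis-aligned planes).
shapeFeatures <- function(mask) {
  fg <- which(mask@voxels != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("mask is empty")
  sp <- mask@spacing
  nvox <- nrow(fg)
  voxVol <- prod(sp)
  V <- nvox * voxVol
  faces <- cpp_exposed_faces(as.numeric(mask@voxels), dim(mask@voxels))
  A <- faces[1] * sp[2] * sp[3] + faces[2] * sp[1] * sp[3] +
       faces[3] * sp[1] * sp[2]

  bnd <- cpp_boundary(as.numeric(mask@voxels), dim(mask@voxels))
  pb <- sweep(bnd, 2, sp, "*")
  maxDiam <- if (nrow(pb) > 1) cpp_max_pairwise(pb) else 0
  planeDiam <- function(fixAxis) {
    groups <- split.data.frame(pb, bnd[, fixAxis])
    m <- vapply(groups, function(g)
      if (nrow(g) > 1) cpp_max_pairwise(as.matrix(g)) else 0, 0)
    max(m)
  }

  coords <- sweep(fg - 1, 2, sp, "*")
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])

  c(MeshVolume = V,
    VoxelVolume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = (36 * pi * V^2)^(1 / 3) / A,
    Maximum3DDiameter = maxDiam,
    Maximum2DDiameterSlice = planeDiam(3),   # axial (xy) plane
    Maximum2DDiameterColumn = planeDiam(2),  # coronal (xz) plane
    Maximum2DDiameterRow = planeDiam(1),     # sagittal (yz) plane
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

# 18 first-order statistics of the in-mask intensities. Entropy and
# Uniformity use a fixed internal 64-bin discretization of the in-mask range
# (first-order features carry no bin-count suffix in the catalogue).
firstorderFeatures <- function(values, voxelVolumeMm3, entropyBins = 64L) {
  n <- length(values)
  if (n == 0) stop("no in-mask values")
  mu <- mean(values)
  p10 <- as.numeric(quantile(values, 0.10, type = 7))
  p90 <- as.numeric(quantile(values, 0.90, type = 7))
  robust <- values[values >= p10 & values <= p90]
  varPop <- mean((values - mu)^2)
  sdPop <- sqrt(varPop)
  if (diff(range(values)) > 0) {
    width <- diff(range(values)) / entropyBins
    b <- pmin(floor((values - min(values)) / width) + 1, entropyBins)
    p <- tabulate(b, entropyBins) / n
    p <- p[p > 0]
  } else p <- 1
  c(Energy = sum(values^2),
    TotalEnergy = voxelVolumeMm3 * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(values),
    Mean = mu,
    Median = median(values),
    InterquartileRange = as.numeric(quantile(values, 0.75, type = 7) -
                                    quantile(values, 0.25, type = 7)),
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (sdPop > 0) mean((values - mu)^3) / sdPop^3 else 0,
    Kurtosis = if (sdPop > 0) mean((values - mu)^4) / sdPop^4 else 0,
    Variance = varPop,
    Uniformity = sum(p^2))
}
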
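#' Resample an image/mask pair to an isotropic grid
#'
#' B-spline interpolation on the image and nearest-neighbour interpolation on
#' the mask, both onto a common isotropic grid covering the same physical
#' extent. Already-isotropic inputs at the target spacing short-circuit.
#'
#' @param image An [ImageVolume-class].
#' @param mask A [RoiMask-class] on the same grid.
#' @param config An [extractionConfig()]; `isoSpacingMm` is used.
#' @return list with resampled `image` and `mask`.
#' @export
preprocessImage <- function(image, mask, config = extractionConfig()) {
  checkSameGrid(image, mask)
  iso <- config@isoSpacingMm
  if (max(abs(image@spacing - iso)) < 1e-9)
    return(list(image = image, mask = mask))
  dims <- dim(image@voxels)
  outDims <- pmax(1L, as.integer(round(dims * image@spacing / iso)))
  # same origin/direction; v_src = diag(iso/spacing) v_out
  A <- diag(iso / image@spacing)
  b <- rep(0, 3)
  coefs <- cpp_bspline_prefilter(as.numeric(image@voxels), dims)
  imgOut <- cpp_resample_affine(coefs, dims, A, b, outDims, 3L, -1000)
  mskOut <- cpp_resample_affine(as.numeric(mask@voxels), dims, A, b, outDims,
                                0L, 0)
  if (sum(mskOut) == 0) stop("mask is empty after isotropic resampling")
  sp <- rep(iso, 3)
  list(image = imageVolume(array(imgOut, outDims), sp, image@origin,
                           image@direction),
       mask = roiMask(array(mskOut, outDims), sp, mask@origin,
                      mask@direction))
}

#' Resegment a mask to an intensity window
#'
#' Removes mask voxels whose (unfiltered) image intensity falls outside
#' `windowHu` — the soft-tissue resegmentation applied before first-order and
#' texture extraction. Shape features keep the morphological mask.
#'
#' @param image The unfiltered [ImageVolume-class].
#' @param mask A nonempty [RoiMask-class].
#' @param windowHu `(low, high)` window in HU.
#' @return The resegmented [RoiMask-class].
#' @export
resegmentMask <- function(image, mask, windowHu = c(-150, 180)) {
  checkSameGrid(image, mask)
  if (sum(mask@voxels) == 0) stop("mask is empty")
  keep <- mask@voxels != 0 & image@voxels >= windowHu[1] &
    image@voxels <= windowHu[2]
  if (!any(keep)) stop("resegmentation emptied the mask")
  roiMask(array(as.numeric(keep), dim(mask@voxels)), mask@spacing,
          mask@origin, mask@direction)
}

#' Fixed-bin-count intensity discretization
#'
#' Maps in-mask intensities to `1..binCount` with equal-width bins spanning
#' the in-mask range; the maximum value is assigned bin `binCount`. A constant
#' region maps to bin 1 everywhere. Voxels outside the mask are 0.
#'
#' @param image An [ImageVolume-class] (any filtered image).
#' @param mask A nonempty [RoiMask-class].
#' @param binCount Number of bins (>= 2).
#' @return Integer array with values 0 (outside) or 1..binCount.
#' @export
discretizeIntensities <- function(image, mask, binCount) {
  stopifnot(binCount >= 2)
  fg <- mask@voxels != 0
  if (!any(fg)) stop("mask is empty")
  x <- image@voxels
  lo <- min(x[fg]); hi <- max(x[fg])
  out <- array(0L, dim(x))
  if (hi == lo) {
    out[fg] <- 1L
  } else {
    width <- (hi - lo) / binCount
    b <- pmin(as.integer(floor((x[fg] - lo) / width)) + 1L, as.integer(binCount))
    out[fg] <- b
  }
  out
}

# --- filter bank ------------------------------------------------------------

# Coiflet-1 decomposition filters, normalized so the low-pass has unit DC
# gain (the stationary LLL subband of a constant image reproduces it).
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645) / sqrt(2)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
              -0.8525720202116004, 0.3848648468648578,
              0.07273261951252645, -0.015655728135791993) / sqrt(2)

# discrete Gaussian and second-derivative-of-Gaussian kernels (unit spacing)
gaussDerivKernel2 <- function(sigmaVox, truncate = 4) {
  r <- max(2L, as.integer(ceiling(truncate * sigmaVox)))
  x <- (-r):r
  g <- exp(-0.5 * (x / sigmaVox)^2)
  g <- g / sum(g)
  k <- g * (x^2 - sigmaVox^2) / sigmaVox^4
  k - mean(k)  # enforce zero DC so constants are annihilated
}

logFilter3d <- function(arr, spacingMm, sigmaMm) {
  sv <- sigmaMm / spacingMm
  g <- lapply(sv, gaussianKernel1d, truncate = 4)
  d2 <- lapply(sv, gaussDerivKernel2)
  dims <- dim(arr)
  x <- as.numeric(arr)
  # scale-normalized LoG: sigma^2 * sum_a d2_a * prod_{b != a} g_b
  out <- cpp_sepconv3(x, dims, d2[[1]], g[[2]], g[[3]]) +
         cpp_sepconv3(x, dims, g[[1]], d2[[2]], g[[3]]) +
         cpp_sepconv3(x, dims, g[[1]], g[[2]], d2[[3]])
  array(sigmaMm^2 * out, dims)
}

waveletFilter3d <- function(arr, subband) {
  stopifnot(nchar(subband) == 3)
  pick <- function(ch) if (ch == "L") COIF1_LO else COIF1_HI
  ks <- lapply(strsplit(subband, "")[[1]], pick)
  array(cpp_sepconv3(as.numeric(arr), dim(arr), ks[[1]], ks[[2]], ks[[3]]),
        dim(arr))
}

logImageName <- function(sigmaMm)
  sprintf("log-sigma-%s-mm-3D", gsub("\\.", "-", format(sigmaMm, nsmall = 1)))

#' Names of the filtered images in the bank
#' @param config An [extractionConfig()].
#' @return Character vector of image names, `original` first.
#' @export
filterBankNames <- function(config = extractionConfig()) {
  nm <- character()
  if ("original" %in% config@filtersEnabled) nm <- c(nm, "original")
  if ("log" %in% config@filtersEnabled)
    nm <- c(nm, vapply(config@logSigmasMm, logImageName, ""))
  if ("wavelet" %in% config@filtersEnabled)
    nm <- c(nm, paste0("wavelet-", config@waveletSubbands))
  nm
}

#' Apply the radiomic filter bank
#'
#' Produces the named set of filtered images: the unfiltered original,
#' scale-normalized 3D Laplacian-of-Gaussian images at the configured sigmas,
#' and single-level stationary (undecimated) Coiflet-1 wavelet subbands, all
#' on the input grid. Requires an isotropic image.
#'
#' @param image A preprocessed (isotropic) [ImageVolume-class].
#' @param config An [extractionConfig()].
#' @return Named list of [ImageVolume-class] objects (12 with defaults).
#' @export
filterBank <- function(image, config = extractionConfig()) {
  if (max(abs(image@spacing - image@spacing[1])) > 1e-6)
    stop("filter bank requires an isotropic image; run preprocessImage first")
  dims <- dim(image@voxels)
  needsFilters <- any(c("log", "wavelet") %in% config@filtersEnabled)
  if (needsFilters && any(dims < 6L))
    stop("image smaller than the filter support")
  wrap <- function(v) imageVolume(v, image@spacing, image@origin,
                                  image@direction)
  out <- list()
  if ("original" %in% config@filtersEnabled) out$original <- image
  if ("log" %in% config@filtersEnabled)
    for (s in config@logSigmasMm)
      out[[logImageName(s)]] <-
        wrap(logFilter3d(image@voxels, image@spacing, s))
  if ("wavelet" %in% config@filtersEnabled)
    for (sb in config@waveletSubbands)
      out[[paste0("wavelet-", sb)]] <- wrap(waveletFilter3d(image@voxels, sb))
  out
}
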
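# --- low-level smoothing helpers -------------------------------------------

gaussianKernel1d <- function(sigmaVox, truncate = 3) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigmaVox)))
  k <- exp(-0.5 * ((-r):r / sigmaVox)^2)
  k / sum(k)
}

# Gaussian transfer function (spectral) for a grid; sigma in voxels per axis
gaussTransfer3d <- function(dims, sigmaVox) {
  tf <- lapply(1:3, function(a) {
    n <- dims[a]
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-2 * pi^2 * sigmaVox[a]^2 * (k / n)^2)
  })
  outer(outer(tf[[1]], tf[[2]]), tf[[3]])
}

# Exact Gaussian smoothing of random fields via the FFT (periodic
# boundaries; cost independent of sigma). Deterministic image filters (LoG,
# wavelet) use FIR kernels with symmetric padding instead.
smoothGaussian3d <- function(arr, spacingMm, sigmaMm) {
  dims <- dim(arr)
  tf <- gaussTransfer3d(dims, sigmaMm / spacingMm)
  Re(stats::fft(stats::fft(arr) * tf, inverse = TRUE)) / prod(dims)
}

# world centroid of the mask foreground
maskCentroidWorld <- function(mask) {
  idx <- which(mask@voxels != 0, arr.ind = TRUE) - 1  # 0-based
  if (nrow(idx) == 0) stop("mask is empty")
  v <- colMeans(idx)
  as.numeric(mask@origin + worldLinear(mask) %*% v)
}

rotationMatrix <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# --- rigid perturbation -----------------------------------------------------

#' Rigid perturbation of an image/mask pair
#'
#' Rotates (about the mask centroid, `Rz Ry Rx` order) and translates image
#' and mask simultaneously, resampling back onto the input grid: cubic
#' B-spline interpolation for the image (with prefiltering), nearest-neighbour
#' for the mask. Out-of-grid voxels are filled with `backgroundHu` (image) and
#' 0 (mask). A zero transform short-circuits to the unmodified inputs.
#'
#' @param image An [ImageVolume-class].
#' @param mask A [RoiMask-class] on the same grid.
#' @param anglesDeg Rotation angles per axis, degrees.
#' @param offsetsMm Translation per axis, mm.
#' @param backgroundHu Fill value for the image outside the source grid.
#' @return list with elements `image` and `mask`.
#' @export
rigidPerturb <- function(image, mask, anglesDeg, offsetsMm,
                         backgroundHu = -1000) {
  checkSameGrid(image, mask)
  if (any(!is.finite(anglesDeg)) || any(!is.finite(offsetsMm)))
    stop("angles and offsets must be finite")
  if (all(anglesDeg == 0) && all(offsetsMm == 0))
    return(list(image = image, mask = mask))
  R <- rotationMatrix(anglesDeg)
  ctr <- maskCentroidWorld(mask)
  W <- worldLinear(image)
  Winv <- solve(W)
  # inverse map: x_src = R^T (x_out - ctr - t) + ctr
  A <- Winv %*% t(R) %*% W
  b <- as.numeric(Winv %*% (t(R) %*% (image@origin - ctr - offsetsMm) +
                            ctr - image@origin))
  dims <- dim(image@voxels)
  coefs <- cpp_bspline_prefilter(as.numeric(image@voxels), dims)
  imgOut <- cpp_resample_affine(coefs, dims, A, b, dims, 3L, backgroundHu)
  mskOut <- cpp_resample_affine(as.numeric(mask@voxels), dims, A, b, dims,
                                0L, 0)
  list(image = imageVolume(array(imgOut, dims), image@spacing, image@origin,
                           image@direction),
       mask = roiMask(array(mskOut, dims), mask@spacing, mask@origin,
                      mask@direction))
}

#' Add an i.i.d. Gaussian noise field to an image
#'
#' Mimics acquisition-to-acquisition noise level variation: zero-mean Gaussian
#' noise of SD `sigmaHu` is added voxel-wise. `sigmaHu = 0` returns the input
#' unchanged; the field is deterministic given the seed.
#'
#' @param image An [ImageVolume-class].
#' @param sigmaHu Noise standard deviation, HU (>= 0).
#' @param seed RNG seed.
#' @return A perturbed [ImageVolume-class].
#' @export
addNoiseField <- function(image, sigmaHu, seed = 1L) {
  if (sigmaHu < 0) stop("sigmaHu must be >= 0")
  if (sigmaHu == 0) return(image)
  dims <- dim(image@voxels)
  noise <- withSeed(seed, rnorm(prod(dims), sd = sigmaHu))
  imageVolume(image@voxels + array(noise, dims), image@spacing,
              image@origin, image@direction)
}

#' Randomize a contour with a deformable vector field
#'
#' Builds a dense random displacement field (white Gaussian noise per axis,
#' smoothed with an isotropic Gaussian of width `smoothnessMm`, rescaled so
#' the mean displacement magnitude over the mask foreground equals
#' `amplitudeMm`) and applies it to the mask by backward warping with
#' nearest-neighbour sampling. Simulates inter-observer delineation
#' variability. `amplitudeMm = 0` returns the input unchanged.
#'
#' @param mask A nonempty [RoiMask-class].
#' @param amplitudeMm Foreground-mean displacement magnitude, mm (>= 0).
#' @param smoothnessMm Gaussian smoothing width of the field, mm.
#' @param seed RNG seed.
#' @return The warped [RoiMask-class].
#' @export
randomizeContour <- function(mask, amplitudeMm, smoothnessMm = 8, seed = 1L) {
  if (amplitudeMm < 0) stop("amplitudeMm must be >= 0")
  fg <- mask@voxels != 0
  if (!any(fg)) stop("mask is empty")
  if (amplitudeMm == 0) return(mask)
  dims <- dim(mask@voxels)
  sp <- mask@spacing
  fields <- withSeed(seed, lapply(1:3, function(a)
    array(rnorm(prod(dims)), dims)))
  tf <- gaussTransfer3d(dims, rep(smoothnessMm, 3) / sp)
  fields <- lapply(fields, function(f)
    Re(stats::fft(stats::fft(f) * tf, inverse = TRUE)) / prod(dims))
  mag <- sqrt(fields[[1]]^2 + fields[[2]]^2 + fields[[3]]^2)
  scale <- amplitudeMm / mean(mag[fg])
  # displacement in mm (world) -> voxel units: diag(1/s) D^T d_mm
  Dt <- t(mask@direction)
  dmm <- lapply(fields, function(f) f * scale)
  dvox <- vector("list", 3)
  for (a in 1:3)
    dvox[[a]] <- (Dt[a, 1] * dmm[[1]] + Dt[a, 2] * dmm[[2]] +
                  Dt[a, 3] * dmm[[3]]) / sp[a]
  out <- cpp_warp_nn(as.numeric(mask@voxels), dims,
                     as.numeric(dvox[[1]]), as.numeric(dvox[[2]]),
                     as.numeric(dvox[[3]]))
  if (sum(out) == 0)
    stop("contour randomization emptied the mask; reduce amplitudeMm")
  roiMask(array(out, dims), sp, mask@origin, mask@direction)
}

# --- mask agreement metrics -------------------------------------------------

#' Dice similarity coefficient between two masks
#'
#' `2|A∩B| / (|A| + |B|)` on a shared grid.
#'
#' @param a,b [RoiMask-class] objects on the same grid.
#' @return Overlap fraction in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  checkSameGrid(a, b, "masks")
  na <- sum(a@voxels); nb <- sum(b@voxels)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a@voxels * b@voxels) / (na + nb)
}

#' Symmetric Hausdorff distance between two masks (mm)
#'
#' Classical (max-min) Hausdorff distance between the boundary voxel sets of
#' the two masks, in mm using the grid spacing.
#'
#' @param a,b Nonempty [RoiMask-class] objects on the same grid.
#' @return Distance in mm.
#' @export
hausdorffDistance <- function(a, b) {
  checkSameGrid(a, b, "masks")
  if (sum(a@voxels) == 0 || sum(b@voxels) == 0)
    stop("Hausdorff distance requires nonempty masks")
  dims <- dim(a@voxels)
  sp <- a@spacing
  ba <- cpp_boundary(as.numeric(a@voxels), dims)
  bb <- cpp_boundary(as.numeric(b@voxels), dims)
  seed <- function(coords) {
    s <- array(0, dims)
    s[coords + 1L] <- 1
    s
  }
  # exact EDT to each boundary, evaluated at the other boundary's voxels
  dToB <- cpp_edt_sq(as.numeric(seed(bb)), dims, sp)
  dToA <- cpp_edt_sq(as.numeric(seed(ba)), dims, sp)
  lin <- function(coords) 1L + coords[, 1] + dims[1] * (coords[, 2] +
                                                        dims[2] * coords[, 3])
  sqrt(max(max(dToB[lin(ba)]), max(dToA[lin(bb)])))
}

# --- amplitude tuner --------------------------------------------------------

#' Tune the DVF amplitude to a target Dice operating point
#'
#' Bisects the displacement amplitude until the mean Dice between original and
#' contour-randomized masks, over patients x a calibration batch of
#' perturbations, is within `tol` of `targetDice`. The same noise draws are
#' reused across amplitude evaluations (the field scales linearly with
#' amplitude), making the objective monotone and the bisection stable.
#'
#' @param masks List of [RoiMask-class] objects (>= 1).
#' @param spec A [perturbationSpec()]; `targetDice` and `dvfSmoothnessMm` are
#'   used.
#' @param calibBatch Perturbation draws per mask per amplitude evaluation.
#' @param maxIter Bisection iteration cap.
#' @param tol Dice tolerance (default 0.01).
#' @return list with `amplitudeMm`, `achievedDice` and `converged` flag (FALSE
#'   when the cap was reached; the best amplitude is still returned).
#' @export
tuneContourAmplitude <- function(masks, spec, calibBatch = 3L, maxIter = 20L,
                                 tol = 0.01) {
  stopifnot(length(masks) >= 1, is(spec, "PerturbationSpec"))
  target <- spec@targetDice
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop("targetDice must be in (0,1)")
  seeds <- deriveSeeds(spec@seed + 1L, length(masks) * calibBatch)
  meanDice <- function(amp) {
    if (amp == 0) return(1)
    s <- 0L; acc <- 0
    for (i in seq_along(masks)) for (j in seq_len(calibBatch)) {
      s <- s + 1L
      pert <- tryCatch(
        randomizeContour(masks[[i]], amp, spec@dvfSmoothnessMm, seeds[s]),
        error = function(e) NULL)
      acc <- acc + if (is.null(pert)) 0 else
        diceCoefficient(masks[[i]], pert)
    }
    acc / s
  }
  lo <- 0; hi <- spec@dvfSmoothnessMm
  while (meanDice(hi) > target && hi < 1e3) hi <- hi * 2
  best <- NULL
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    d <- meanDice(mid)
    if (is.null(best) || abs(d - target) < abs(best$achievedDice - target))
      best <- list(amplitudeMm = mid, achievedDice = d)
    if (abs(d - target) <= tol) { converged <- TRUE; break }
    if (d > target) lo <- mid else hi <- mid
  }
  if (!converged)
    warnf("amplitude tuner hit the iteration cap; best Dice %.3f for target %.3f",
          best$achievedDice, target)
  c(best, list(converged = converged))
}

# --- full perturbation simulation ------------------------------------------

#' Simulate a set of perturbed image/contour samples for a cohort
#'
#' For each perturbation index, draws rotation angles and translation offsets
#' uniformly within the spec ranges, a Gaussian noise field and a DVF; applies
#' rigid -> noise to the image and rigid -> DVF to the mask (perturbation is
#' applied before any preprocessing). Draws are independent per patient by
#' default; with `sharedDraws = TRUE` the same draw is reused across patients
#' for a given index. If `dvfAmplitudeMm` is `NA` the amplitude is first tuned
#' on the cohort masks to the spec's `targetDice`.
#'
#' @param cohort A cohort list (entries with `image`, `mask`, `patientId`).
#' @param spec A [perturbationSpec()].
#' @return list of class `PerturbationSet`: per patient, a list of perturbed
#'   samples (`index`, `image`, `mask`, `params`); the realized amplitude is
#'   stored in the `amplitudeMm` attribute.
#' @export
simulatePerturbationSet <- function(cohort, spec) {
  stopifnot(is(spec, "PerturbationSpec"))
  validObject(spec)
  amp <- spec@dvfAmplitudeMm
  if (is.na(amp)) {
    tuned <- tuneContourAmplitude(lapply(cohort, `[[`, "mask"), spec)
    amp <- tuned$amplitudeMm
  }
  nP <- spec@nPerturbations
  n <- length(cohort)
  drawParams <- function(s) withSeed(s, list(
    angles = runif(3, -spec@rotationDegRange, spec@rotationDegRange),
    offsets = runif(3, -spec@translationMmRange, spec@translationMmRange),
    noiseSeed = sample.int(.Machine$integer.max - 1L, 1L),
    dvfSeed = sample.int(.Machine$integer.max - 1L, 1L)))
  if (spec@sharedDraws) {
    seeds <- deriveSeeds(spec@seed, nP)
    shared <- lapply(seeds, drawParams)
  } else {
    seeds <- matrix(deriveSeeds(spec@seed, n * nP), n, nP)
  }
  out <- lapply(seq_len(n), function(i) {
    entry <- cohort[[i]]
    lapply(seq_len(nP), function(j) {
      par <- if (spec@sharedDraws) shared[[j]] else drawParams(seeds[i, j])
      rig <- rigidPerturb(entry$image, entry$mask, par$angles, par$offsets)
      img <- addNoiseField(rig$image, spec@noiseSigmaHu, par$noiseSeed)
      msk <- if (amp > 0)
        randomizeContour(rig$mask, amp, spec@dvfSmoothnessMm, par$dvfSeed)
      else rig$mask
      list(index = j - 1L, image = img, mask = msk,
           params = c(par, list(amplitudeMm = amp)))
    })
  })
  names(out) <- vapply(cohort, function(p) p$patientId %||% "", "")
  structure(out, class = "PerturbationSet", amplitudeMm = amp, spec = spec)
}
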
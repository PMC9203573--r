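#' @title Parameter objects
#' @name ipbm-params
#' @description S4 parameter containers for the phantom generator, the
#'   perturbation protocol, feature extraction and feature selection. Each has
#'   a constructor with the package defaults and a validity method enforcing
#'   the documented invariants.
NULL

#' @rdname ipbm-params
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  nPatients = "integer", gridShape = "integer", spacingMm = "numeric",
  lesionRadiusRangeMm = "numeric", textureCorrelationLengthMm = "numeric",
  textureAmplitudeHu = "numeric", hazardCoefficients = "numeric",
  censoringRate = "numeric", backgroundHu = "numeric", lesionMeanHu = "numeric",
  weibullShape = "numeric", weibullScaleMonths = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nPatients < 2L) msg <- c(msg, "n_patients must be >= 2")
    if (object@censoringRate < 0 || object@censoringRate > 1)
      msg <- c(msg, "censoring_rate must be in [0,1]")
    if (length(object@lesionRadiusRangeMm) != 2L ||
        diff(object@lesionRadiusRangeMm) < 0 ||
        any(object@lesionRadiusRangeMm <= 0))
      msg <- c(msg, "lesion radius range must be positive (min, max)")
    # lesion must fit fully inside the grid with >= 5 mm margin
    halfExtent <- min(object@gridShape * object@spacingMm) / 2
    if (max(object@lesionRadiusRangeMm) + 5 > halfExtent)
      msg <- c(msg, sprintf(
        "lesion (max radius %.1f mm) cannot fit in the grid with a 5 mm margin (half-extent %.1f mm)",
        max(object@lesionRadiusRangeMm), halfExtent))
    if (length(msg)) msg else TRUE
  })

#' Phantom cohort configuration
#'
#' Defines a synthetic CT-like cohort: each patient has an ellipsoidal lesion
#' over a soft-tissue background, filled with a smoothed Gaussian random-field
#' texture. The per-patient texture amplitude and correlation length are the
#' latent predictors driving a Weibull proportional-hazards survival outcome.
#'
#' @param nPatients Number of patients (>= 2).
#' @param gridShape Voxels per axis.
#' @param spacingMm Voxel size per axis, mm.
#' @param lesionRadiusRangeMm Range (min, max) of ellipsoid semi-axes, mm.
#' @param textureCorrelationLengthMm Gaussian correlation length of the lesion
#'   texture, mm.
#' @param textureAmplitudeHu Texture standard deviation inside the lesion, HU.
#' @param hazardCoefficients Named log-hazard effect sizes for the latent
#'   predictors `amplitude` and `corlength` (standardized scale).
#' @param censoringRate Target fraction of censored patients in [0,1].
#' @param backgroundHu,lesionMeanHu Background and lesion mean intensity, HU.
#' @param weibullShape,weibullScaleMonths Baseline Weibull hazard parameters.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return A `PhantomConfig` object.
#' @export
phantomConfig <- function(nPatients = 100L,
                          gridShape = c(64L, 64L, 64L),
                          spacingMm = c(1, 1, 1),
                          lesionRadiusRangeMm = c(15, 25),
                          textureCorrelationLengthMm = 4,
                          textureAmplitudeHu = 30,
                          hazardCoefficients = c(amplitude = 0.8,
                                                 corlength = 0),
                          censoringRate = 0.6,
                          backgroundHu = 40,
                          lesionMeanHu = 60,
                          weibullShape = 1.2,
                          weibullScaleMonths = 40,
                          seed = 1L) {
  new("PhantomConfig", nPatients = as.integer(nPatients),
      gridShape = as.integer(gridShape), spacingMm = as.numeric(spacingMm),
      lesionRadiusRangeMm = as.numeric(lesionRadiusRangeMm),
      textureCorrelationLengthMm = textureCorrelationLengthMm,
      textureAmplitudeHu = textureAmplitudeHu,
      hazardCoefficients = hazardCoefficients,
      censoringRate = censoringRate, backgroundHu = backgroundHu,
      lesionMeanHu = lesionMeanHu, weibullShape = weibullShape,
      weibullScaleMonths = weibullScaleMonths, seed = as.integer(seed))
}

#' @rdname ipbm-params
#' @exportClass VarianceComponentSpec
setClass("VarianceComponentSpec", representation(
  nSubjects = "integer", nRaters = "integer", sigmaBetween = "numeric",
  sigmaWithin = "numeric", mu = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 2L) msg <- c(msg, "n_subjects must be >= 2")
    if (object@nRaters < 2L) msg <- c(msg, "n_raters must be >= 2")
    if (object@sigmaBetween < 0 || object@sigmaWithin < 0)
      msg <- c(msg, "standard deviations must be >= 0")
    if (object@sigmaBetween == 0 && object@sigmaWithin == 0)
      msg <- c(msg, "at least one variance component must be positive")
    if (length(msg)) msg else TRUE
  })

#' Variance-component specification for ICC fixtures
#'
#' Describes the one-way random-effects model
#' `x_ij = mu + b_i + e_ij`, `b_i ~ N(0, sigmaBetween^2)`,
#' `e_ij ~ N(0, sigmaWithin^2)`, whose true intraclass correlation is
#' `sigmaBetween^2 / (sigmaBetween^2 + sigmaWithin^2)`.
#'
#' @param nSubjects,nRaters Matrix dimensions (subjects x raters).
#' @param sigmaBetween,sigmaWithin Between-/within-subject SD (>= 0).
#' @param mu Grand mean.
#' @param seed RNG seed.
#' @return A `VarianceComponentSpec` object.
#' @export
varianceComponentSpec <- function(nSubjects, nRaters, sigmaBetween,
                                  sigmaWithin, mu = 0, seed = 1L) {
  new("VarianceComponentSpec", nSubjects = as.integer(nSubjects),
      nRaters = as.integer(nRaters), sigmaBetween = sigmaBetween,
      sigmaWithin = sigmaWithin, mu = mu, seed = as.integer(seed))
}

#' True ICC of a variance-component specification
#' @param spec A [varianceComponentSpec()] object.
#' @return The population ICC in [0, 1].
#' @export
trueIcc <- function(spec) {
  spec@sigmaBetween^2 / (spec@sigmaBetween^2 + spec@sigmaWithin^2)
}

#' @rdname ipbm-params
#' @exportClass PerturbationSpec
setClass("PerturbationSpec", representation(
  nPerturbations = "integer", rotationDegRange = "numeric",
  translationMmRange = "numeric", noiseSigmaHu = "numeric",
  dvfAmplitudeMm = "numeric", dvfSmoothnessMm = "numeric",
  targetDice = "numeric", sharedDraws = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nPerturbations < 2L)
      msg <- c(msg, "n_perturbations must be >= 2 (ICC needs >= 2 raters)")
    if (any(c(object@rotationDegRange, object@translationMmRange,
              object@noiseSigmaHu, object@dvfSmoothnessMm) < 0))
      msg <- c(msg, "ranges and SDs must be >= 0")
    if (!is.na(object@dvfAmplitudeMm) && object@dvfAmplitudeMm < 0)
      msg <- c(msg, "dvf amplitude must be >= 0")
    if (!is.na(object@targetDice) &&
        (object@targetDice <= 0 || object@targetDice >= 1))
      msg <- c(msg, "target Dice must be in (0,1)")
    if (length(msg)) msg else TRUE
  })

#' Perturbation protocol
#'
#' Randomization magnitudes for simulating internal validation data: per
#' perturbation a rigid transform (uniform rotations/translations) applied to
#' image and mask together, an i.i.d. Gaussian noise field added to the image,
#' and a random deformable vector field (DVF) applied to the mask only.
#' `dvfAmplitudeMm = NA` means the amplitude is tuned at simulation time so the
#' mean Dice overlap against the original contours hits `targetDice`.
#'
#' @param nPerturbations Number of perturbed sets per patient (default 60).
#' @param rotationDegRange Symmetric per-axis rotation bound, degrees.
#' @param translationMmRange Symmetric per-axis translation bound, mm.
#' @param noiseSigmaHu SD of the additive Gaussian noise field, HU.
#' @param dvfAmplitudeMm Mean foreground displacement magnitude of the DVF, mm
#'   (NA: tune to `targetDice`).
#' @param dvfSmoothnessMm Gaussian smoothing width of the DVF, mm.
#' @param targetDice Dice operating point used when tuning the amplitude.
#' @param sharedDraws If TRUE, perturbation index i uses the same parameter
#'   draw for all patients; default FALSE (independent draws per patient).
#' @param seed Master seed.
#' @return A `PerturbationSpec` object.
#' @export
perturbationSpec <- function(nPerturbations = 60L, rotationDegRange = 15,
                             translationMmRange = 5, noiseSigmaHu = 20,
                             dvfAmplitudeMm = NA_real_, dvfSmoothnessMm = 16,
                             targetDice = 0.85, sharedDraws = FALSE,
                             seed = 1L) {
  new("PerturbationSpec", nPerturbations = as.integer(nPerturbations),
      rotationDegRange = rotationDegRange,
      translationMmRange = translationMmRange, noiseSigmaHu = noiseSigmaHu,
      dvfAmplitudeMm = as.numeric(dvfAmplitudeMm),
      dvfSmoothnessMm = dvfSmoothnessMm, targetDice = targetDice,
      sharedDraws = sharedDraws, seed = as.integer(seed))
}

#' @rdname ipbm-params
#' @exportClass ExtractionConfig
setClass("ExtractionConfig", representation(
  isoSpacingMm = "numeric", resegmentationWindowHu = "numeric",
  binCounts = "integer", logSigmasMm = "numeric",
  waveletSubbands = "character", filtersEnabled = "character",
  familiesEnabled = "character", textureFamilies = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@binCounts < 2L))
      msg <- c(msg, "bin counts must be positive integers >= 2")
    if (length(object@resegmentationWindowHu) != 2L ||
        diff(object@resegmentationWindowHu) <= 0)
      msg <- c(msg, "resegmentation window must satisfy low < high")
    if (!all(object@familiesEnabled %in% c("shape", "firstorder", "texture")))
      msg <- c(msg, "unknown feature family")
    if (!all(object@textureFamilies %in%
             c("glcm", "glrlm", "glszm", "gldm", "ngtdm")))
      msg <- c(msg, "unknown texture family")
    if (!all(object@filtersEnabled %in% c("original", "log", "wavelet")))
      msg <- c(msg, "unknown filter class")
    if (length(msg)) msg else TRUE
  })

#' Radiomic extraction configuration
#'
#' Defaults reproduce the 5,486-feature catalogue: a 12-image filter bank
#' (original, 3 Laplacian-of-Gaussian scales, 8 Coiflet-1 stationary wavelet
#' subbands), 14 shape + 18 first-order features per image, and 73 texture
#' features per image per bin count over 6 fixed bin counts.
#'
#' @param isoSpacingMm Isotropic resampling target, mm.
#' @param resegmentationWindowHu Soft-tissue window applied to the intensity
#'   mask before first-order/texture extraction.
#' @param binCounts Fixed bin counts for texture discretization.
#' @param logSigmasMm Laplacian-of-Gaussian scales, mm.
#' @param waveletSubbands Stationary Coiflet-1 subbands to include.
#' @param filtersEnabled Which filter classes feed the bank.
#' @param familiesEnabled Feature families to extract.
#' @param textureFamilies Texture matrix families.
#' @return An `ExtractionConfig` object.
#' @export
extractionConfig <- function(isoSpacingMm = 1,
                             resegmentationWindowHu = c(-150, 180),
                             binCounts = c(4L, 8L, 16L, 32L, 64L, 128L),
                             logSigmasMm = c(1, 3, 6),
                             waveletSubbands = c("LLL", "HLL", "LHL", "LLH",
                                                 "LHH", "HLH", "HHL", "HHH"),
                             filtersEnabled = c("original", "log", "wavelet"),
                             familiesEnabled = c("shape", "firstorder",
                                                 "texture"),
                             textureFamilies = c("glcm", "glrlm", "glszm",
                                                 "gldm", "ngtdm")) {
  new("ExtractionConfig", isoSpacingMm = isoSpacingMm,
      resegmentationWindowHu = as.numeric(resegmentationWindowHu),
      binCounts = as.integer(binCounts), logSigmasMm = as.numeric(logSigmasMm),
      waveletSubbands = waveletSubbands, filtersEnabled = filtersEnabled,
      familiesEnabled = familiesEnabled, textureFamilies = textureFamilies)
}

#' @rdname ipbm-params
#' @exportClass SelectionConfig
setClass("SelectionConfig", representation(
  nBootstrap = "integer", logrankAlpha = "numeric", topFraction = "numeric",
  corrThreshold = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@topFraction <= 0 || object@topFraction > 1)
      msg <- c(msg, "top_fraction must be in (0,1]")
    if (object@logrankAlpha <= 0 || object@logrankAlpha >= 1)
      msg <- c(msg, "logrank_alpha must be in (0,1)")
    if (object@corrThreshold <= 0 || object@corrThreshold >= 1)
      msg <- c(msg, "corr_threshold must be in (0,1)")
    if (object@nBootstrap < 1L) msg <- c(msg, "n_bootstrap must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Feature-selection configuration
#'
#' Two-stage filter selection: balanced-subsample bootstrap log-rank relevance
#' filtering (features with p < `logrankAlpha` counted per iteration, top
#' `topFraction` by frequency retained) followed by pairwise Pearson
#' correlation redundancy filtering at `corrThreshold`.
#'
#' @param nBootstrap Bootstrap iterations (default 100).
#' @param logrankAlpha Per-iteration log-rank significance level.
#' @param topFraction Fraction of features kept after relevance ranking.
#' @param corrThreshold Absolute Pearson correlation above which a feature
#'   pair is redundant.
#' @param seed RNG seed for the bootstrap draws.
#' @return A `SelectionConfig` object.
#' @export
selectionConfig <- function(nBootstrap = 100L, logrankAlpha = 0.1,
                            topFraction = 0.10, corrThreshold = 0.6,
                            seed = 1L) {
  new("SelectionConfig", nBootstrap = as.integer(nBootstrap),
      logrankAlpha = logrankAlpha, topFraction = topFraction,
      corrThreshold = corrThreshold, seed = as.integer(seed))
}
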
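#' Extract radiomic features from a preprocessed image/mask pair
#'
#' Shape features come from the morphological mask (no filter, no bin count).
#' The mask is resegmented once to the soft-tissue window on the unfiltered
#' image; first-order features are computed per filtered image on the
#' resegmented (undiscretized) intensities, and texture features per filtered
#' image per bin count on the fixed-bin-count discretized intensities.
#' Feature names follow the `<image>_<family>_<feature>[_<bin>_binCount]`
#' convention, e.g. `wavelet-LLL_glrlm_RunEntropy_128_binCount`.
#'
#' @param image A preprocessed (isotropic) [ImageVolume-class].
#' @param mask The morphological [RoiMask-class] on the same grid.
#' @param config An [extractionConfig()].
#' @param engine Optional plug-in extractor `function(image, mask, config)`
#'   returning a named feature vector under the same naming convention; when
#'   supplied it replaces the built-in engine.
#' @return Named numeric feature vector.
#' @export
extractFeatures <- function(image, mask, config = extractionConfig(),
                            engine = NULL) {
  if (!is.null(engine)) return(engine(image, mask, config))
  checkSameGrid(image, mask)
  if (sum(mask@voxels) == 0) stop("mask is empty")
  out <- numeric()
  if ("shape" %in% config@familiesEnabled) {
    sf <- shapeFeatures(mask)
    out <- c(out, setNames(sf, paste0("original_shape_", names(sf))))
  }
  intensityFam <- intersect(c("firstorder", "texture"),
                            config@familiesEnabled)
  if (length(intensityFam)) {
    rmask <- resegmentMask(image, mask, config@resegmentationWindowHu)
    bank <- filterBank(image, config)
    fg <- rmask@voxels != 0
    np <- sum(fg)
    voxVol <- prod(image@spacing)
    dims <- dim(image@voxels)
    for (imgName in names(bank)) {
      vox <- bank[[imgName]]@voxels
      if ("firstorder" %in% intensityFam) {
        fo <- firstorderFeatures(vox[fg], voxVol)
        out <- c(out, setNames(fo, paste0(imgName, "_firstorder_",
                                          names(fo))))
      }
      if ("texture" %in% intensityFam) {
        filtImg <- imageVolume(vox, image@spacing, image@origin,
                               image@direction)
        for (bc in config@binCounts) {
          disc <- discretizeIntensities(filtImg, rmask, bc)
          ng <- max(disc)
          vals <- list()
          if ("glcm" %in% config@textureFamilies)
            vals$glcm <- glcmFeatures(cpp_glcm(disc, dims, ng))
          if ("glrlm" %in% config@textureFamilies)
            vals$glrlm <- glrlmFeatures(cpp_glrlm(disc, dims, ng), np)
          if ("glszm" %in% config@textureFamilies)
            vals$glszm <- glszmFeatures(cpp_glszm(disc, dims, ng), np)
          if ("gldm" %in% config@textureFamilies)
            vals$gldm <- gldmFeatures(cpp_gldm(disc, dims, ng, 0L))
          if ("ngtdm" %in% config@textureFamilies) {
            nt <- cpp_ngtdm(disc, dims, ng)
            vals$ngtdm <- ngtdmFeatures(nt$s, nt$n)
          }
          for (fam in names(vals))
            out <- c(out, setNames(vals[[fam]],
                                   sprintf("%s_%s_%s_%d_binCount", imgName,
                                           fam, names(vals[[fam]]), bc)))
        }
      }
    }
  }
  out
}

#' Enumerate the feature inventory of a configuration
#'
#' Deterministic ordered list of the feature names the extractor produces.
#' With defaults the counts decompose as 14 shape + 18 first-order x 12
#' images + 73 texture x 12 images x 6 bin counts = 5,486.
#'
#' @param config An [extractionConfig()].
#' @return Character vector of feature names.
#' @export
enumerateInventory <- function(config = extractionConfig()) {
  shapeNames <- c("MeshVolume", "VoxelVolume", "SurfaceArea",
                  "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
                  "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
                  "Maximum2DDiameterRow", "MajorAxisLength",
                  "MinorAxisLength", "LeastAxisLength", "Elongation",
                  "Flatness")
  foNames <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
               "90Percentile", "Maximum", "Mean", "Median",
               "InterquartileRange", "Range", "MeanAbsoluteDeviation",
               "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
               "Kurtosis", "Variance", "Uniformity")
  famNames <- textureFeatureNames()
  images <- filterBankNames(config)
  out <- character()
  if ("shape" %in% config@familiesEnabled)
    out <- c(out, paste0("original_shape_", shapeNames))
  for (imgName in images) {
    if ("firstorder" %in% config@familiesEnabled)
      out <- c(out, paste0(imgName, "_firstorder_", foNames))
    if ("texture" %in% config@familiesEnabled)
      for (bc in config@binCounts)
        for (fam in intersect(c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                              config@textureFamilies))
          out <- c(out, sprintf("%s_%s_%s_%d_binCount", imgName, fam,
                                famNames[[fam]], bc))
  }
  out
}

#' Parse a feature name into its components
#'
#' @param names Character vector of catalogue-style feature names.
#' @return data.frame with columns `image`, `filterFamily` (`original`,
#'   `log-sigma`, `wavelet`), `family`, `feature` and `binCount` (NA where not
#'   applicable).
#' @export
parseFeatureName <- function(names) {
  parts <- strsplit(names, "_")
  img <- vapply(parts, `[[`, "", 1)
  fam <- vapply(parts, `[[`, "", 2)
  feat <- vapply(parts, `[[`, "", 3)
  bin <- vapply(parts, function(p)
    if (length(p) >= 5 && p[length(p)] == "binCount")
      as.integer(p[length(p) - 1]) else NA_integer_, 0L)
  filterFamily <- ifelse(startsWith(img, "log-sigma"), "log-sigma",
                  ifelse(startsWith(img, "wavelet"), "wavelet", "original"))
  data.frame(image = img, filterFamily = filterFamily, family = fam,
             feature = feat, binCount = bin, stringsAsFactors = FALSE)
}

#' Extract a cohort feature table
#'
#' Runs preprocessing and extraction for each cohort entry and assembles the
#' patients x features matrix. All-constant columns are retained here;
#' modelling entry points drop them with a warning.
#'
#' @param cohort Cohort list (entries with `patientId`, `image`, `mask`).
#' @param config An [extractionConfig()].
#' @param engine Optional plug-in extractor (see [extractFeatures()]).
#' @param preprocess If FALSE the entries are assumed already isotropic.
#' @return Numeric matrix with patient ids as row names.
#' @export
extractFeatureTable <- function(cohort, config = extractionConfig(),
                                engine = NULL, preprocess = TRUE) {
  rows <- lapply(cohort, function(p) {
    pair <- if (preprocess) preprocessImage(p$image, p$mask, config)
            else list(image = p$image, mask = p$mask)
    extractFeatures(pair$image, pair$mask, config, engine)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- vapply(cohort, function(p) p$patientId %||% "", "")
  tab
}

#' Extract feature tables for every perturbation of a perturbation set
#'
#' @param perturbationSet Output of [simulatePerturbationSet()].
#' @param config An [extractionConfig()].
#' @param engine Optional plug-in extractor.
#' @param preprocess Resample each perturbed pair to isotropic spacing first.
#' @return list of feature matrices, one per perturbation index, each with
#'   patients as rows.
#' @export
extractPerturbedFeatureTables <- function(perturbationSet,
                                          config = extractionConfig(),
                                          engine = NULL, preprocess = TRUE) {
  nP <- length(perturbationSet[[1]])
  pids <- names(perturbationSet)
  lapply(seq_len(nP), function(j) {
    rows <- lapply(perturbationSet, function(samples) {
      s <- samples[[j]]
      pair <- if (preprocess) preprocessImage(s$image, s$mask, config)
              else list(image = s$image, mask = s$mask)
      extractFeatures(pair$image, pair$mask, config, engine)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- pids
    tab
  })
}
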
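#' Read a NIfTI volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param asMask If TRUE return a [RoiMask-class] (any nonzero voxel is
#'   foreground), otherwise an [ImageVolume-class].
#' @return An `ImageVolume` or `RoiMask`.
#' @export
readVolumeNifti <- function(path, asMask = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  dir <- aff[1:3, 1:3] %*% diag(1 / sp)
  org <- aff[1:3, 4]
  vox <- array(as.numeric(img), dim = dim(img)[1:3])
  if (asMask) roiMask(vox, sp, org, dir) else imageVolume(vox, sp, org, dir)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as uint8 label volumes; images as 32-bit float.
#'
#' @param vol An `ImageVolume` or `RoiMask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolumeNifti <- function(vol, path) {
  dt <- if (is(vol, "RoiMask")) "uint8" else "float"
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- worldLinear(vol)
  aff[1:3, 4] <- vol@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write a cohort to disk as NIfTI pairs plus a manifest
#'
#' The manifest CSV has columns `patient_id`, `image`, `mask`, `time_months`,
#' `event` — the same entry point used for real cohorts.
#'
#' @param cohort A `PhantomCohort` (or compatible list).
#' @param dir Output directory (created if missing).
#' @return Path to the written `manifest.csv`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(p) {
    imgFile <- paste0(p$patientId, "_image.nii.gz")
    mskFile <- paste0(p$patientId, "_mask.nii.gz")
    writeVolumeNifti(p$image, file.path(dir, imgFile))
    writeVolumeNifti(p$mask, file.path(dir, mskFile))
    data.frame(patient_id = p$patientId, image = imgFile, mask = mskFile,
               time_months = p$outcome$timeMonths, event = p$outcome$event)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest CSV (paths relative to its directory), loads every
#' image/mask pair, and validates the geometry: identical grid shape, spacing
#' agreement within 1e-4 mm and origin agreement within 1e-3 mm. Rows with a
#' missing outcome are rejected with a report; geometry mismatches and empty
#' masks are hard errors naming the patient.
#'
#' @param manifestPath Path to a manifest CSV with columns `patient_id`,
#'   `image`, `mask`, `time_months`, `event`.
#' @return A list of per-patient entries (`patientId`, `image`, `mask`,
#'   `outcome`), in manifest row order, with the manifest as an attribute.
#' @export
loadCohort <- function(manifestPath) {
  if (!file.exists(manifestPath)) stopf("manifest not found: %s", manifestPath)
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("patient_id", "image", "mask", "time_months", "event")
  if (!all(need %in% names(man)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  bad <- is.na(man$time_months) | is.na(man$event)
  if (any(bad)) {
    warnf("rejected %d row(s) with missing outcome: %s", sum(bad),
          paste(man$patient_id[bad], collapse = ", "))
    man <- man[!bad, , drop = FALSE]
  }
  if (!all(man$event %in% c(0, 1)))
    stopf("event column must be 0/1; offending patients: %s",
          paste(man$patient_id[!man$event %in% c(0, 1)], collapse = ", "))
  if (any(man$time_months < 0)) stop("time_months must be nonnegative")
  base <- dirname(manifestPath)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  cohort <- lapply(seq_len(nrow(man)), function(i) {
    pid <- man$patient_id[i]
    img <- readVolumeNifti(resolve(man$image[i]))
    msk <- readVolumeNifti(resolve(man$mask[i]), asMask = TRUE)
    ok <- tryCatch(checkSameGrid(img, msk), error = function(e)
      stopf("patient %s: %s", pid, conditionMessage(e)))
    if (sum(msk@voxels) == 0) stopf("patient %s: mask is empty", pid)
    list(patientId = pid, image = img, mask = msk,
         outcome = list(timeMonths = man$time_months[i],
                        event = as.integer(man$event[i])))
  })
  structure(cohort, class = "PhantomCohort", manifest = man)
}

#' Stratified train/test split
#'
#' Splits patients into train and test with stratification by event status:
#' within each class, `round(testFraction * n_class)` patients go to test, so
#' the event ratio in each split is within one patient of exact
#' proportionality. Deterministic given the seed.
#'
#' @param outcomes data.frame with columns `patient_id` and `event` (e.g. from
#'   [cohortOutcomes()]).
#' @param testFraction Fraction assigned to the test split (default 0.30).
#' @param seed RNG seed.
#' @return list with character vectors `train` and `test` of patient ids.
#' @export
stratifiedSplit <- function(outcomes, testFraction = 0.30, seed = 1L) {
  stopifnot(testFraction >= 0, testFraction <= 1)
  ids <- as.character(outcomes$patient_id)
  ev <- outcomes$event
  if (testFraction == 0) return(list(train = ids, test = character()))
  if (testFraction == 1) return(list(train = character(), test = ids))
  classes <- split(ids, ev)
  if (length(classes) < 2L)
    stop("both event classes must be present for a stratified split")
  if (any(lengths(classes) < 2L))
    stop("each event class needs at least 2 members")
  test <- withSeed(seed, {
    unlist(lapply(classes, function(cl) {
      nTest <- round(testFraction * length(cl))
      sample(cl, nTest)
    }), use.names = FALSE)
  })
  list(train = ids[!ids %in% test], test = ids[ids %in% test])
}
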
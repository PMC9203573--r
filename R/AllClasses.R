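#' @title Core S4 classes
#' @name ipbm-classes
#' @description
#' `ImageVolume` and `RoiMask` are geometric 3D grids: a voxel array plus
#' spacing (mm), origin (mm) and a 3x3 orthonormal direction matrix.
#' Continuous voxel indices are 0-based with voxel centres at integer
#' coordinates; world coordinates follow the NIfTI convention
#' `world = origin + direction %*% (spacing * index)`.
NULL

setClass("VoxelGrid", representation("VIRTUAL",
  voxels = "array", spacing = "numeric", origin = "numeric",
  direction = "matrix"))

validVoxelGrid <- function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  D <- object@direction
  if (!all(dim(D) == c(3L, 3L)) ||
      max(abs(crossprod(D) - diag(3))) > 1e-6)
    msg <- c(msg, "direction must be a 3x3 orthonormal matrix (tol 1e-6)")
  if (length(msg)) msg else TRUE
}

#' @rdname ipbm-classes
#' @exportClass ImageVolume
setClass("ImageVolume", contains = "VoxelGrid", validity = validVoxelGrid)

#' @rdname ipbm-classes
#' @exportClass RoiMask
setClass("RoiMask", contains = "VoxelGrid", validity = function(object) {
  v <- validVoxelGrid(object)
  if (!isTRUE(v)) return(v)
  if (!all(object@voxels %in% c(0, 1)))
    return("mask voxels must be binary (0/1)")
  TRUE
})

#' Construct an image volume
#'
#' @param voxels 3D numeric array of intensities (HU for CT-like data).
#' @param spacing Per-axis voxel size in mm.
#' @param origin World coordinate (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction cosine matrix.
#' @return An [ImageVolume-class] object.
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' Construct a binary ROI mask
#'
#' Any nonzero voxel is treated as foreground (tolerant of 255-coded masks).
#'
#' @inheritParams imageVolume
#' @return A [RoiMask-class] object.
#' @export
roiMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    direction = diag(3)) {
  v <- array(as.numeric(voxels != 0), dim = dim(voxels))
  new("RoiMask", voxels = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' @rdname ipbm-classes
#' @param object,x A `VoxelGrid` object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ipbm-classes
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname ipbm-classes
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname ipbm-classes
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname ipbm-classes
setMethod("voxels", "VoxelGrid", function(x) x@voxels)
#' @rdname ipbm-classes
setMethod("spacing", "VoxelGrid", function(x) x@spacing)
#' @rdname ipbm-classes
setMethod("origin", "VoxelGrid", function(x) x@origin)
#' @rdname ipbm-classes
setMethod("direction", "VoxelGrid", function(x) x@direction)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume %dx%dx%d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("RoiMask %dx%dx%d voxels, spacing %s mm, %d foreground voxels\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              sum(object@voxels)))
})

# --- geometry helpers (internal) -------------------------------------------

# 3x3 voxel-to-world linear part
worldLinear <- function(x) x@direction %*% diag(x@spacing)

sameGrid <- function(a, b) {
  identical(dim(a@voxels), dim(b@voxels)) &&
    max(abs(a@spacing - b@spacing)) <= 1e-4 &&
    max(abs(a@origin - b@origin)) <= 1e-3 &&
    max(abs(a@direction - b@direction)) <= 1e-6
}

checkSameGrid <- function(a, b, what = "image and mask") {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stopf("%s differ in grid shape", what)
  if (max(abs(a@spacing - b@spacing)) > 1e-4)
    stopf("%s differ in spacing (tol 1e-4 mm)", what)
  if (max(abs(a@origin - b@origin)) > 1e-3)
    stopf("%s differ in origin (tol 1e-3 mm)", what)
  if (max(abs(a@direction - b@direction)) > 1e-6)
    stopf("%s differ in direction", what)
  invisible(TRUE)
}

# --- ICC result -------------------------------------------------------------

#' @rdname ipbm-classes
#' @exportClass ICCResult
setClass("ICCResult", representation(
  estimate = "numeric", ciLow = "numeric", ciHigh = "numeric",
  nSubjects = "integer", nRaters = "integer", label = "character"),
  validity = function(object) {
    if (object@ciLow > object@estimate + 1e-12 ||
        object@estimate > object@ciHigh + 1e-12)
      return("CI must bracket the estimate after clamping")
    TRUE
  })

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(1,1) = %.3f (95%% CI %.3f-%.3f), n = %d subjects x %d raters: %s reliability\n",
              object@estimate, object@ciLow, object@ciHigh,
              object@nSubjects, object@nRaters, object@label))
})

# --- Cox model --------------------------------------------------------------

#' @rdname ipbm-classes
#' @exportClass CoxModel
setClass("CoxModel", representation(
  features = "character", coefficients = "numeric", penalty = "numeric",
  center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (!length(object@features)) return("feature list must be non-empty")
    if (any(!is.finite(object@coefficients)))
      return("coefficients must be finite")
    if (length(object@coefficients) != length(object@features))
      return("one coefficient per feature required")
    if (object@penalty < 0) return("penalty must be nonnegative")
    TRUE
  })

setMethod("show", "CoxModel", function(object) {
  cat(sprintf("Ridge-penalized Cox model: %d features, penalty %.4g\n",
              length(object@features), object@penalty))
  print(setNames(round(object@coefficients, 4), object@features))
})

#' @rdname ipbm-classes
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname ipbm-classes
setMethod("featureNames", "CoxModel", function(x) x@features)
#' @rdname ipbm-classes
#' @export
setMethod("coef", "CoxModel",
          function(object) setNames(object@coefficients, object@features))
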
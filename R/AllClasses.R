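#' @useDynLib SymSlice, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' VolumeGrid: a 3D scalar intensity lattice with physical spacing
#'
#' The central container of the pipeline: a 3D array of intensities
#' (modality-dependent units) together with the physical voxel spacing in
#' millimetres along each axis.
#'
#' @slot intensities numeric 3D array, dimensions `(n_x, n_y, n_z)`.
#' @slot spacing numeric length-3, mm per voxel along x, y, z; all positive.
#' @export
setClass("VolumeGrid",
  representation(intensities = "array", spacing = "numeric"))

setValidity("VolumeGrid", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L) return("intensities must be a 3D array")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacings must be finite and > 0")
  TRUE
})

#' Construct a VolumeGrid
#'
#' @param intensities numeric 3D array of voxel intensities.
#' @param spacing numeric length-3 physical spacing (mm/voxel).
#' @return A [VolumeGrid-class] object. Intensities are promoted to double.
#' @examples
#' v <- VolumeGrid(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' isIsotropic(v)
#' @export
VolumeGrid <- function(intensities, spacing = c(1, 1, 1)) {
  storage.mode(intensities) <- "double"
  new("VolumeGrid", intensities = intensities, spacing = as.numeric(spacing))
}

#' DicomSeriesMeta: slice-ordering and spacing metadata of a DICOM series
#'
#' @slot instanceNumbers integer vector, the InstanceNumber of each slice in
#'   stacking order (ascending).
#' @slot pixelSpacing numeric length-2, in-plane mm/pixel (row, column).
#' @slot sliceThickness numeric scalar, slice-to-slice spacing in mm.
#' @export
setClass("DicomSeriesMeta",
  representation(instanceNumbers = "integer", pixelSpacing = "numeric",
                 sliceThickness = "numeric"))

setValidity("DicomSeriesMeta", function(object) {
  if (anyDuplicated(object@instanceNumbers))
    return("instance numbers must be distinct")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    return("sliceThickness must be a positive scalar")
  TRUE
})

#' IntensityThresholds: the two Otsu thresholds bounding the organ band
#'
#' @slot tLow,tHigh numeric scalars with `tLow < tHigh`; voxels with
#'   intensity in `[tLow, tHigh]` are taken as organ.
#' @export
setClass("IntensityThresholds",
  representation(tLow = "numeric", tHigh = "numeric"))

setValidity("IntensityThresholds", function(object) {
  if (!is.finite(object@tLow) || !is.finite(object@tHigh))
    return("thresholds must be finite")
  if (object@tLow >= object@tHigh) return("tLow must be < tHigh")
  TRUE
})

#' Plane: a plane in voxel coordinates
#'
#' The plane is \eqn{\{x : n \cdot x = d\}} with unit normal `n`.
#'
#' @slot normal unit length-3 vector.
#' @slot offset scalar `d` (voxel units).
#' @export
setClass("Plane", representation(normal = "numeric", offset = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@normal) != 3L) return("normal must have length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be a unit vector")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    return("offset must be a finite scalar")
  TRUE
})

#' @rdname Plane-class
#' @param normal length-3 vector (normalized internally).
#' @param offset scalar plane offset.
#' @return A [Plane-class].
#' @export
Plane <- function(normal, offset = 0) {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("plane normal must be nonzero")
  new("Plane", normal = n / nn, offset = as.numeric(offset))
}

#' RigidTransform: a proper rigid motion x -> R x + t
#'
#' @slot rotation 3x3 rotation matrix (orthonormal, det +1).
#' @slot translation length-3 vector.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal within 1e-6")
  if (abs(det(R) - 1) > 1e-6) return("rotation must have det +1 within 1e-6")
  if (length(object@translation) != 3L) return("translation must have length 3")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return A [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' SymmetryPlane: estimated plane of best bilateral symmetry
#'
#' The plane of best symmetry together with the two in-plane axes that frame
#' the representative slice, and the ICP registration residual.
#'
#' @slot plane the [Plane-class] (unit normal + offset, voxel units).
#' @slot axisU,axisV unit in-plane axes; `normal`, `axisU`, `axisV` are
#'   mutually orthonormal and right-handed (`normal = axisU x axisV`).
#' @slot residualRMS final ICP point-distance RMS (voxel units).
#' @export
setClass("SymmetryPlane",
  representation(plane = "Plane", axisU = "numeric", axisV = "numeric",
                 residualRMS = "numeric"))

setValidity("SymmetryPlane", function(object) {
  B <- cbind(object@plane@normal, object@axisU, object@axisV)
  if (max(abs(crossprod(B) - diag(3))) > 1e-6)
    return("normal, axisU, axisV must be mutually orthonormal within 1e-6")
  TRUE
})

#' SliceFrame: raster frame of the plane-sampled 2D image
#'
#' @slot origin length-3 point (voxel units) at the centre of the raster.
#' @slot axisU,axisV orthonormal in-plane axes.
#' @slot uRange,vRange length-2 `(min, max)` extents of the raster along
#'   each axis, relative to `origin` (voxel units).
#' @slot pixelStep sampling step (voxel units per raster sample).
#' @export
setClass("SliceFrame",
  representation(origin = "numeric", axisU = "numeric", axisV = "numeric",
                 uRange = "numeric", vRange = "numeric", pixelStep = "numeric"))

setValidity("SliceFrame", function(object) {
  if (abs(sum(object@axisU * object@axisV)) > 1e-6)
    return("axisU and axisV must be orthogonal within 1e-6")
  for (r in list(object@uRange, object@vRange))
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      return("ranges must be finite with min < max")
  if (object@pixelStep <= 0) return("pixelStep must be positive")
  TRUE
})

#' RepresentativeImage: the 224x224 8-bit image on the symmetry plane
#'
#' @slot pixels integer matrix, exactly 224x224, values in `[0, 255]`.
#' @export
setClass("RepresentativeImage", representation(pixels = "matrix"))

setValidity("RepresentativeImage", function(object) {
  p <- object@pixels
  if (!all(dim(p) == c(224L, 224L))) return("pixels must be 224x224")
  if (min(p) < 0 || max(p) > 255) return("pixel values must lie in [0, 255]")
  if (any(p != round(p))) return("pixel values must be integers")
  TRUE
})

#' PerturbationSpec: bounds for random orientation perturbations
#'
#' @slot rotationRangeDeg per-axis rotation bound in degrees (draws are
#'   uniform in the symmetric interval).
#' @slot translationRange per-axis translation bound in isotropic voxels.
#' @slot seed integer RNG seed.
#' @export
setClass("PerturbationSpec",
  representation(rotationRangeDeg = "numeric", translationRange = "numeric",
                 seed = "integer"))

setValidity("PerturbationSpec", function(object) {
  if (object@rotationRangeDeg < 0 || object@translationRange < 0)
    return("perturbation bounds must be >= 0")
  TRUE
})

#' @rdname PerturbationSpec-class
#' @param rotationRangeDeg rotation bound (degrees), default 15.
#' @param translationRange translation bound (voxels), default 5.
#' @param seed RNG seed.
#' @return A [PerturbationSpec-class].
#' @export
PerturbationSpec <- function(rotationRangeDeg = 15, translationRange = 5,
                             seed = 1L) {
  new("PerturbationSpec", rotationRangeDeg = as.numeric(rotationRangeDeg),
      translationRange = as.numeric(translationRange), seed = as.integer(seed))
}

#' DatasetSplit: train/test partition with derived perturbed test sets
#'
#' Volumes are held by reference (the list passed to [buildDatasets]);
#' perturbed variants are materialized on demand by [splitSet] from per-item
#' seeds so the split object stays small and fully reproducible.
#'
#' @slot volumes list of [VolumeGrid-class] (isotropic).
#' @slot labels factor of class labels, one per volume.
#' @slot trainIdx,testIdx integer indices into `volumes`.
#' @slot augmentKind character, one of `"rigid"`/`"swap"` per training item
#'   (the 50/50 augmentation rule).
#' @slot spec the [PerturbationSpec-class] used for derived sets.
#' @slot itemSeeds integer matrix of per-item derived seeds.
#' @export
setClass("DatasetSplit",
  representation(volumes = "list", labels = "factor", trainIdx = "integer",
                 testIdx = "integer", augmentKind = "character",
                 spec = "PerturbationSpec", itemSeeds = "matrix"))

#' MetricReport: macro-averaged classification metrics
#'
#' Accuracy is micro (trace/total); sensitivity, specificity, precision,
#' F-measure and G-mean are one-vs-rest per class, then averaged (macro).
#'
#' @slot accuracy,sensitivity,specificity,precision,fMeasure,gMean scalars
#'   in `[0, 1]`.
#' @slot perClass data.frame of the per-class values.
#' @slot flagged character vector of classes whose precision denominator was
#'   zero (contributing 0 to the macro mean).
#' @export
setClass("MetricReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", precision = "numeric",
                 fMeasure = "numeric", gMean = "numeric",
                 perClass = "data.frame", flagged = "character"))
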
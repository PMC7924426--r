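#' @describeIn accessors the intensity array of a `VolumeGrid`.
#' @export
setMethod("intensities", "VolumeGrid", function(object) object@intensities)

#' @describeIn accessors the physical spacing (mm/voxel) of a `VolumeGrid`.
#' @export
setMethod("spacing", "VolumeGrid", function(object) object@spacing)

#' @describeIn accessors `TRUE` if all three spacings are equal within
#'   `1e-9` relative tolerance.
#' @export
setMethod("isIsotropic", "VolumeGrid", function(object) {
  s <- object@spacing
  all(abs(s - s[1]) <= 1e-9 * s[1])
})

#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@intensities))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VolumeGrid: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm%s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3],
              if (isIsotropic(object)) " [isotropic]" else ""))
  r <- range(object@intensities)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", r[1], r[2]))
})

#' @describeIn accessors unit normal of a `Plane`.
#' @export
setMethod("planeNormal", "Plane", function(object) object@normal)

#' @describeIn accessors offset of a `Plane`.
#' @export
setMethod("planeOffset", "Plane", function(object) object@offset)

setMethod("show", "Plane", function(object) {
  cat(sprintf("Plane: n = (%.4f, %.4f, %.4f), d = %.3f\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@offset))
})

#' @describeIn accessors unit normal of the plane held by a `SymmetryPlane`.
#' @export
setMethod("planeNormal", "SymmetryPlane", function(object) object@plane@normal)

#' @describeIn accessors offset of the plane held by a `SymmetryPlane`.
#' @export
setMethod("planeOffset", "SymmetryPlane", function(object) object@plane@offset)

#' @describeIn accessors first in-plane axis of a `SymmetryPlane`.
#' @export
setMethod("axisU", "SymmetryPlane", function(object) object@axisU)

#' @describeIn accessors second in-plane axis of a `SymmetryPlane`.
#' @export
setMethod("axisV", "SymmetryPlane", function(object) object@axisV)

#' @describeIn accessors post-ICP RMS residual of a `SymmetryPlane` (voxels).
#' @export
setMethod("residualRMS", "SymmetryPlane", function(object) object@residualRMS)

setMethod("show", "SymmetryPlane", function(object) {
  n <- object@plane@normal
  cat(sprintf("SymmetryPlane: n = (%.4f, %.4f, %.4f), d = %.3f, residual RMS %.4f\n",
              n[1], n[2], n[3], object@plane@offset, object@residualRMS))
})

#' @describeIn accessors pixel matrix of a `RepresentativeImage`.
#' @export
setMethod("pixels", "RepresentativeImage", function(object) object@pixels)

setMethod("show", "RepresentativeImage", function(object) {
  cat(sprintf("RepresentativeImage: 224 x 224, 8-bit, mean intensity %.1f\n",
              mean(object@pixels)))
})

#' @describeIn accessors the `(tLow, tHigh)` pair of an `IntensityThresholds`.
#' @export
setMethod("thresholds", "IntensityThresholds",
          function(object) c(tLow = object@tLow, tHigh = object@tHigh))

setMethod("show", "IntensityThresholds", function(object) {
  cat(sprintf("IntensityThresholds: [%.4g, %.4g]\n", object@tLow, object@tHigh))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (accuracy micro; other metrics macro over classes):\n")
  v <- c(Accuracy = object@accuracy, Sensitivity = object@sensitivity,
         Specificity = object@specificity, Precision = object@precision,
         `F-Measure` = object@fMeasure, `G-Mean` = object@gMean)
  print(round(v, 4))
  if (length(object@flagged))
    cat("  zero-denominator classes:", paste(object@flagged, collapse = ", "),
        "\n")
})

#' Convert a MetricReport to a one-row data frame
#'
#' Columns follow the conventional table order: Accuracy, Sensitivity,
#' Specificity, Precision, F-Measure, G-Mean.
#'
#' @param x a [MetricReport-class].
#' @param row.names,optional,... ignored (S3 signature).
#' @return one-row `data.frame`.
#' @export
as.data.frame.MetricReport <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(Accuracy = x@accuracy, Sensitivity = x@sensitivity,
             Specificity = x@specificity, Precision = x@precision,
             F.Measure = x@fMeasure, G.Mean = x@gMean)
}
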
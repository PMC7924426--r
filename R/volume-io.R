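#' Resample a volume to an isotropic grid
#'
#' Resamples so that all three voxel spacings equal the x spacing, using
#' cubic (Keys) interpolation. The output array size is
#' \deqn{[n_x,\; \mathrm{round}(n_y \, ps_y / ps_x),\;
#'        \mathrm{round}(n_z \, st / ps_x)]}
#' where \eqn{(ps_x, ps_y, st)} is the input spacing: every axis is
#' renormalized to the x pixel spacing, so physical extent is preserved
#' within one voxel. Non-integer sizes are rounded half away from zero
#' (minimum 1); samples falling outside the input grid are clamped to the
#' nearest edge voxel, which avoids ringing at the borders.
#'
#' @param v a [VolumeGrid-class] with positive finite spacing.
#' @param order interpolation order: 3 (cubic, default), 1 (trilinear) or
#'   0 (nearest).
#' @return an isotropic [VolumeGrid-class] with spacing
#'   `(ps_x, ps_x, ps_x)`.
#' @examples
#' v <- VolumeGrid(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(0.5, 0.5, 2))
#' dim(resampleIsotropic(v))   # 8 x 8 x 16
#' @export
resampleIsotropic <- function(v, order = 3L) {
  stopifnot(is(v, "VolumeGrid"))
  sp <- v@spacing
  if (!all(is.finite(sp)) || any(sp <= 0))
    stop("non-finite or non-positive spacing")
  d <- dim(v@intensities)
  scale <- sp / sp[1]                       # (1, ps_y/ps_x, st/ps_x)
  # round half away from zero (sizes are positive, so floor(x + .5))
  out_dim <- pmax(1L, as.integer(floor(d * scale + 0.5)))
  # output voxel index i maps to input index i / scale (0-based centres)
  A <- diag(1 / scale)
  out <- .resampleAffineCpp(v@intensities, as.integer(d), A, c(0, 0, 0),
                            out_dim, as.integer(order), 0, TRUE)
  VolumeGrid(out, spacing = rep(sp[1], 3))
}

#' Read a volume from disk
#'
#' @param path file path.
#' @param format `"nifti"` (NIfTI-1, spacing from the header `pixdim`) or
#'   `"rds"` (the package's internal compressed array container, as written
#'   by [writeVolume]).
#' @return a [VolumeGrid-class].
#' @export
readVolume <- function(path, format = c("nifti", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("NIfTI format error in ", path,
                                             ": ", conditionMessage(e)))
    if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume in ", path)
    a <- array(as.vector(img), dim(img))   # strip niftiImage attributes
    VolumeGrid(a, spacing = RNifti::pixdim(img)[1:3])
  } else {
    obj <- tryCatch(readRDS(path),
                    error = function(e) stop("array-container format error in ",
                                             path, ": ", conditionMessage(e)))
    if (!is.list(obj) || is.null(obj$intensities) || is.null(obj$spacing))
      stop("array-container format error in ", path,
           ": missing intensities/spacing")
    VolumeGrid(obj$intensities, spacing = obj$spacing)
  }
}

#' Write a volume to disk
#'
#' @param v a [VolumeGrid-class].
#' @param path output file path.
#' @param format `"nifti"` or `"rds"` (internal compressed array container;
#'   exact round-trip of intensities and spacing).
#' @return invisibly, `path`.
#' @export
writeVolume <- function(v, path, format = c("nifti", "rds")) {
  stopifnot(is(v, "VolumeGrid"))
  format <- match.arg(format)
  if (format == "nifti") {
    img <- RNifti::asNifti(v@intensities)
    RNifti::pixdim(img) <- v@spacing
    RNifti::writeNifti(img, path)
  } else {
    saveRDS(list(intensities = v@intensities, spacing = v@spacing), path)
  }
  invisible(path)
}

#' Write a point cloud as xyz text or ASCII PLY
#'
#' @param points N x 3 numeric matrix of coordinates.
#' @param path output path.
#' @param format `"xyz"` (whitespace-separated) or `"ply"` (ASCII).
#' @return invisibly, `path`.
#' @export
writePointCloud <- function(points, path, format = c("xyz", "ply")) {
  format <- match.arg(format)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (format == "xyz") {
    utils::write.table(points, path, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(points)),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    utils::write.table(points, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
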
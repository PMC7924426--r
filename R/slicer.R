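#' Build the raster frame of the symmetry-plane image
#'
#' Projects reference vertices onto the in-plane axes; the raster bounds
#' are the min/max of these projections and the raster origin is the plane
#' point at the middle of the bounds. The sampling step is chosen so that
#' the longer bound spans `rasterSize` samples; the shorter axis is
#' implicitly zero-padded when the square image is sampled.
#'
#' By default (`points = NULL`) the reference vertices are the 8 corners of
#' the volume box. Because the box does not rotate with the imaged content,
#' its projected extents - and hence the raster scale - vary with the
#' orientation of the recovered axes; passing the segmented point cloud as
#' `points` anchors the bounds to the content instead, which is
#' rigid-equivariant and is what [extractRepresentative] uses to keep the
#' representative slice orientation-stable.
#'
#' @param v an isotropic [VolumeGrid-class].
#' @param s a [SymmetryPlane-class].
#' @param rasterSize raster width in samples (default 224).
#' @param points optional N x 3 matrix of reference points (e.g. the organ
#'   point cloud) whose projections define the bounds; `NULL` = the volume
#'   box vertices.
#' @param widthSD when `points` is a cloud, the raster half-width per axis
#'   is `widthSD` standard deviations of the projections (default 2.4,
#'   covering a disc profile with ~20% margin), centred at the midpoint of
#'   their 5th/95th percentiles. Whole-distribution statistics are immune
#'   to the segmentation strays (partial-volume halos of artifact specks)
#'   and edge-membership noise that make raw min/max bounds
#'   orientation-unstable. Ignored for box vertices.
#' @return a [SliceFrame-class] with ranges centred on the origin.
#' @export
buildFrame <- function(v, s, rasterSize = 224L, points = NULL,
                       widthSD = 2.4) {
  stopifnot(is(v, "VolumeGrid"), is(s, "SymmetryPlane"))
  if (!isIsotropic(v)) stop("buildFrame expects an isotropic volume")
  d <- dim(v@intensities)
  corners <- if (is.null(points)) {
    as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  } else as.matrix(points)
  n <- s@plane@normal
  base <- s@plane@offset * n           # a point on the plane
  rel <- sweep(corners, 2, base)
  up <- drop(rel %*% s@axisU)
  vp <- drop(rel %*% s@axisV)
  if (max(abs(s@axisU)) < 1e-9 || max(abs(s@axisV)) < 1e-9)
    stop("degenerate frame axes")
  bound <- function(p) {
    if (is.null(points)) return(range(p))
    ctr <- mean(stats::quantile(p, c(0.05, 0.95), names = FALSE))
    ctr + c(-1, 1) * widthSD * stats::sd(p)
  }
  ub <- bound(up)
  vb <- bound(vp)
  umid <- mean(ub)
  vmid <- mean(vb)
  origin <- base + umid * s@axisU + vmid * s@axisV
  ur <- ub - umid
  vr <- vb - vmid
  step <- max(diff(ur), diff(vr)) / rasterSize
  new("SliceFrame", origin = origin, axisU = s@axisU, axisV = s@axisV,
      uRange = ur, vRange = vr, pixelStep = step)
}

#' Sample the 2D image lying on a plane through the volume
#'
#' Raster sample \eqn{(i, j)} lies at
#' \eqn{origin + u_i\,axisU + v_j\,axisV}; its value is the intensity of the
#' nearest voxel (every in-volume sample equals some voxel's intensity
#' exactly). Samples outside the volume are filled with 0.
#'
#' @param v an isotropic [VolumeGrid-class].
#' @param f a [SliceFrame-class].
#' @param square if `TRUE` (default) a square raster covering the longer
#'   range on both axes is sampled (so the shorter axis is symmetrically
#'   zero-padded); if `FALSE` the raster covers exactly `uRange` x `vRange`.
#' @param canonicalize if `TRUE`, flip the image along each axis so the
#'   intensity centre of mass lies on the non-negative side (deterministic
#'   resolution of the u/-u, v/-v sign ambiguity; default `FALSE`).
#' @return numeric matrix (u along rows, v along columns).
#' @export
extractPlaneImage <- function(v, f, square = TRUE, canonicalize = FALSE) {
  stopifnot(is(v, "VolumeGrid"), is(f, "SliceFrame"))
  step <- f@pixelStep
  if (square) {
    half <- max(diff(f@uRange), diff(f@vRange)) / 2
    ur <- c(-half, half) + mean(f@uRange)
    vr <- c(-half, half) + mean(f@vRange)
  } else {
    ur <- f@uRange
    vr <- f@vRange
  }
  nu <- as.integer(floor(diff(ur) / step + 1e-9)) + 1L
  nv <- as.integer(floor(diff(vr) / step + 1e-9)) + 1L
  us <- ur[1] + (seq_len(nu) - 1L) * step
  vs <- vr[1] + (seq_len(nv) - 1L) * step
  g <- expand.grid(u = us, v = vs)
  pts <- cbind(f@origin[1] + g$u * f@axisU[1] + g$v * f@axisV[1],
               f@origin[2] + g$u * f@axisU[2] + g$v * f@axisV[2],
               f@origin[3] + g$u * f@axisU[3] + g$v * f@axisV[3])
  img <- matrix(.sampleNearestCpp(v@intensities, dim(v@intensities), pts, 0),
                nrow = nu, ncol = nv)
  if (canonicalize) img <- .canonicalize_flips(img)
  img
}

# flip each axis so the intensity centre of mass (above the image minimum)
# is on the non-negative side of the raster centre
.canonicalize_flips <- function(img) {
  w <- img - min(img)
  tw <- sum(w)
  if (tw > 0) {
    nr <- nrow(img)
    nc <- ncol(img)
    cu <- sum(rowSums(w) * seq_len(nr)) / tw
    cv <- sum(colSums(w) * seq_len(nc)) / tw
    if (cu < (nr + 1) / 2) img <- img[nr:1, , drop = FALSE]
    if (cv < (nc + 1) / 2) img <- img[, nc:1, drop = FALSE]
  }
  img
}

#' Normalize a plane image to the classifier input format
#'
#' Linearly rescales intensities from `[min, max]` to `[0, 255]` (a constant
#' image becomes all zeros), pads the shorter axis symmetrically with zeros
#' to a square, resizes to `size` x `size` with bilinear interpolation, and
#' rounds to 8-bit integers.
#'
#' @param img numeric matrix.
#' @param size output side length (default 224).
#' @return a [RepresentativeImage-class].
#' @export
normalizeImage <- function(img, size = 224L) {
  img <- as.matrix(img)
  if (length(img) == 0) stop("empty image")
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) * 255
         else array(0, dim(img))
  d <- dim(img)
  if (d[1] != d[2]) {
    side <- max(d)
    sq <- matrix(0, side, side)
    o1 <- (side - d[1]) %/% 2
    o2 <- (side - d[2]) %/% 2
    sq[o1 + seq_len(d[1]), o2 + seq_len(d[2])] <- img
    img <- sq
  }
  img <- .resize_bilinear(img, size)
  px <- round(img)
  px[px < 0] <- 0
  px[px > 255] <- 255
  storage.mode(px) <- "integer"
  new("RepresentativeImage", pixels = px)
}

# align-corners bilinear resize of a matrix to size x size
.resize_bilinear <- function(img, size) {
  d <- dim(img)
  if (all(d == size)) return(img)
  A <- diag(3) * 0
  A[1, 1] <- if (size > 1) (d[1] - 1) / (size - 1) else 0
  A[2, 2] <- if (size > 1) (d[2] - 1) / (size - 1) else 0
  A[3, 3] <- 1
  out <- .resampleAffineCpp(array(img, c(d, 1L)), as.integer(c(d, 1L)), A,
                            c(0, 0, 0), as.integer(c(size, size, 1L)), 1L, 0,
                            TRUE)
  matrix(out, size, size)
}

#' Write a RepresentativeImage as an 8-bit grayscale PNG
#'
#' @param ri a [RepresentativeImage-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRepresentativeImage <- function(ri, path) {
  stopifnot(is(ri, "RepresentativeImage"))
  png::writePNG(ri@pixels / 255, path)
  invisible(path)
}

#' Normalized cross-correlation between two images, maximized over shifts
#'
#' Pearson correlation of the overlapping regions, maximized over integer
#' shifts up to `maxLag` in both axes (coarse-to-fine: step-2 scan then a
#' +/-1 refinement). Used to quantify how similar two representative slices
#' are irrespective of small residual translations.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param maxLag maximum shift searched per axis (default 12).
#' @return scalar in `[-1, 1]`.
#' @export
nccImages <- function(a, b, maxLag = 12L) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  corr_at <- function(di, dj) {
    nr <- nrow(a); nc <- ncol(a)
    i1 <- max(1, 1 + di):min(nr, nr + di)
    j1 <- max(1, 1 + dj):min(nc, nc + dj)
    av <- a[i1, j1]
    bv <- b[i1 - di, j1 - dj]
    sa <- stats::sd(av); sb <- stats::sd(bv)
    if (sa == 0 || sb == 0) return(0)
    stats::cor(as.vector(av), as.vector(bv))
  }
  best <- c(0L, 0L)
  bv <- corr_at(0L, 0L)
  for (di in seq(-maxLag, maxLag, by = 2L)) {
    for (dj in seq(-maxLag, maxLag, by = 2L)) {
      v <- corr_at(di, dj)
      if (v > bv) { bv <- v; best <- c(di, dj) }
    }
  }
  for (di in best[1] + (-1:1)) {
    for (dj in best[2] + (-1:1)) {
      if (abs(di) > maxLag || abs(dj) > maxLag) next
      v <- corr_at(di, dj)
      if (v > bv) bv <- v
    }
  }
  bv
}
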
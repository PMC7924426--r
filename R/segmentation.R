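#' Two-threshold Otsu thresholds of a volume histogram
#'
#' Multi-level global Otsu thresholding with two thresholds: the intensity
#' histogram is partitioned into three classes (background / organ band /
#' bright extreme) and the pair of thresholds maximizing the between-class
#' variance (equivalently minimizing the within-class variance) is found by
#' exhaustive search over all bin pairs. Ties are broken towards the
#' lexicographically smallest `(tLow, tHigh)`.
#'
#' @param v a [VolumeGrid-class] (or a numeric array/vector of intensities)
#'   with at least 3 distinct values.
#' @param bins number of histogram bins over `[min, max]` (default 256, the
#'   conventional resolution for 8-bit work).
#' @return an [IntensityThresholds-class]; the thresholds are the bin edges
#'   separating the three classes, so the organ band is `[tLow, tHigh]`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 10, 1), rnorm(300, 100, 1), rnorm(300, 200, 1))
#' thresholds(otsuTwoThresholds(array(x, c(10, 10, 9))))
#' @export
otsuTwoThresholds <- function(v, bins = 256L) {
  x <- if (is(v, "VolumeGrid")) v@intensities else v
  x <- as.numeric(x)
  rng <- range(x)
  if (length(unique(x)) < 3)
    stop("degenerate histogram: need at least 3 distinct intensity values")
  bins <- as.integer(bins)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- .bin_counts(x, rng, bins)
  sel <- .otsu_search(h)
  new("IntensityThresholds", tLow = edges[sel[1] + 1L],
      tHigh = edges[sel[2] + 1L])
}

# histogram counts over [rng] with `bins` equal bins, right-closed top bin
.bin_counts <- function(x, rng, bins) {
  idx <- pmin(bins, pmax(1L, floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L))
  tabulate(idx, nbins = bins)
}

# exhaustive search over threshold bin pairs (i < j): classes are bins
# [1..i], (i..j], (j..B].  Returns c(i, j) maximizing between-class variance;
# first maximum in (i, j) scan order = lexicographically smallest pair.
.otsu_search <- function(h) {
  B <- length(h)
  p <- h / sum(h)
  mids <- seq_len(B) - 0.5
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  total_mean <- cm[B]
  best <- c(1L, 2L)
  best_val <- -Inf
  for (i in seq_len(B - 2L)) {
    w1 <- cw[i]
    m1 <- cm[i]
    js <- (i + 1L):(B - 1L)
    w2 <- cw[js] - w1
    w3 <- 1 - cw[js]
    m2 <- cm[js] - m1
    m3 <- total_mean - cm[js]
    # between-class variance, guarding empty classes
    v <- ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    jbest <- which.max(v)
    if (v[jbest] > best_val) {
      best_val <- v[jbest]
      best <- c(i, js[jbest])
    }
  }
  best
}

#' Segment the organ band of a volume
#'
#' Marks voxels whose intensity lies within `[tLow, tHigh]` (closed
#' interval) as organ, excluding imaging artifacts at both extremes of the
#' intensity spectrum, and returns the coordinates of the selected voxels as
#' a point cloud in 0-based isotropic-voxel units.
#'
#' @param v an isotropic [VolumeGrid-class].
#' @param t an [IntensityThresholds-class] from [otsuTwoThresholds].
#' @return `list(mask = logical 3D array, cloud = N x 3 numeric matrix)`.
#' @export
segmentBand <- function(v, t) {
  stopifnot(is(v, "VolumeGrid"), is(t, "IntensityThresholds"))
  if (!isIsotropic(v))
    stop("segmentBand expects an isotropic volume; run resampleIsotropic first")
  a <- v@intensities
  mask <- a >= t@tLow & a <= t@tHigh
  if (!any(mask))
    stop("empty segmentation: no voxel intensities within [",
         format(t@tLow), ", ", format(t@tHigh), "]")
  idx <- which(mask, arr.ind = TRUE)
  cloud <- matrix(as.numeric(idx - 1L), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  list(mask = mask, cloud = cloud)
}
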
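#' Reflect a point cloud about a plane
#'
#' Each point \eqn{x} maps to \eqn{x - 2 (n \cdot x - d)\, n}; equivalently
#' the affine map with matrix \eqn{H = I - 2 n n^T} and offset \eqn{2 d n}.
#' `H` is an involution with determinant \eqn{-1}.
#'
#' @param points N x 3 numeric matrix.
#' @param p a [Plane-class].
#' @return N x 3 matrix of reflected points.
#' @export
reflectPoints <- function(points, p) {
  stopifnot(is(p, "Plane"))
  points <- as.matrix(points)
  n <- p@normal
  s <- drop(points %*% n) - p@offset
  points - 2 * outer(s, n)
}

# reflection as an affine map (H, b): x -> H x + b
.reflection_affine <- function(p) {
  n <- p@normal
  list(H = diag(3) - 2 * tcrossprod(n), b = 2 * p@offset * n)
}

#' Rigidly register two point clouds with ICP
#'
#' Point-to-point iterative closest point: alternates nearest-neighbour
#' correspondence (transformed source to target, via a uniform-grid spatial
#' index) with a closed-form rigid update (cross-covariance SVD with
#' determinant correction), until the relative change in RMS distance falls
#' below `tol` or `maxIter` is reached. Each update re-fits the composite
#' transform from the original source, so the result maps source directly
#' into the target frame.
#'
#' @param source,target N x 3 / M x 3 numeric matrices (non-empty).
#' @param maxIter maximum iterations (default 50).
#' @param tol relative RMS-change convergence tolerance (default 1e-4).
#' @param maxPoints a source cloud larger than this is uniformly subsampled
#'   (default 5000) for efficiency; the target cloud is kept whole (the
#'   spatial index is cheap), so the residual measures true mismatch rather
#'   than subsample spacing.
#' @param seed RNG seed for the subsample (default 1).
#' @return `list(transform = RigidTransform, residualRMS, history)` where
#'   `history` is the per-iteration RMS (non-increasing up to numerical
#'   tolerance).
#' @export
icpRegister <- function(source, target, maxIter = 50L, tol = 1e-4,
                        maxPoints = 5000L, seed = 1L) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) == 0 || nrow(target) == 0)
    stop("ICP requires non-empty point clouds")
  if (nrow(source) > maxPoints) {
    set.seed(seed)
    source <- source[sample.int(nrow(source), maxPoints), , drop = FALSE]
  }
  res <- .icpCpp(source, target, as.integer(maxIter), tol)
  list(transform = RigidTransform(res$rotation, res$translation),
       residualRMS = res$rms, history = res$history)
}

# orthonormal in-plane axes from the principal axes of the cloud projected
# onto the plane, ordered by decreasing in-plane variance and right-handed
# with the normal (n = u x v).  Stable under rigid motion of the cloud,
# unlike the (degenerate) eigenvalue-1 eigenvectors of a near-exact
# reflection.
.inplane_axes <- function(points, n) {
  e <- .orth_complement(n)
  ctr <- colMeans(points)
  P <- sweep(points, 2, ctr) %*% e            # N x 2 in-plane coordinates
  C <- crossprod(P) / nrow(P)
  eg <- eigen(C, symmetric = TRUE)
  u <- drop(e %*% eg$vectors[, 1])
  u <- u / sqrt(sum(u^2))
  v <- .cross3(n, u)
  list(u = u, v = v)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# two unit vectors spanning the orthogonal complement of unit n (3 x 2)
.orth_complement <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  cbind(e1, .cross3(n, e1))
}

# deterministic sign: first component larger than 1e-8 in absolute value
# is made positive
.canonical_sign <- function(n) {
  for (i in 1:3) if (abs(n[i]) > 1e-8) return(if (n[i] < 0) -n else n)
  n
}

#' Estimate the plane of best bilateral symmetry of a point cloud
#'
#' Implements the reflect-register-eigendecompose construction: the cloud is
#' reflected about an initial plane, the reflection is rigidly registered to
#' the original with ICP, and the composite map \eqn{S(x) = M x + c} (with
#' \eqn{M = R H_0}, \eqn{c = R b_0 + t}) is eigen-decomposed. For a cloud
#' that is symmetric about some plane, \eqn{S} is the reflection about that
#' plane, so \eqn{M} has eigenvalues \eqn{\{-1, 1, 1\}}: the eigenvector of
#' the eigenvalue nearest \eqn{-1} is the plane normal and the offset is
#' \eqn{d = (n \cdot c)/2}. Because ICP is a local method, the initial plane
#' is multi-started over the three principal axes of the cloud (through its
#' centroid) and the candidate with the lowest ICP residual is kept. The
#' in-plane frame `axisU`/`axisV` is taken from the principal axes of the
#' cloud projected onto the plane (ordered by in-plane variance,
#' right-handed), which is stable where the eigenvalue-1 eigenspace of a
#' near-exact reflection is not.
#'
#' @param points N x 3 matrix with at least 4 non-coplanar points.
#' @param maxIter,tol,maxPoints,seed ICP parameters, see [icpRegister].
#' @return a [SymmetryPlane-class]. Always returns the best-effort plane;
#'   the registration quality is reported in `residualRMS`.
#' @examples
#' set.seed(7)
#' half <- matrix(runif(300, 0, 10), ncol = 3)
#' cloud <- rbind(half, sweep(half, 2, c(-1, 1, 1), "*"))  # symmetric in x=0
#' planeNormal(bestSymmetryPlane(cloud))
#' @export
bestSymmetryPlane <- function(points, maxIter = 50L, tol = 1e-4,
                              maxPoints = 5000L, seed = 1L) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  ctr <- colMeans(points)
  pc <- eigen(stats::cov(points), symmetric = TRUE)$vectors
  best <- NULL
  errors <- character(0)
  for (k in 1:3) {
    n0 <- pc[, k]
    p0 <- Plane(n0, sum(n0 * ctr))
    cand <- tryCatch({
      refl <- reflectPoints(points, p0)
      reg <- icpRegister(refl, points, maxIter = maxIter, tol = tol,
                         maxPoints = maxPoints, seed = seed)
      list(p0 = p0, reg = reg)
    }, error = function(e) e)
    if (inherits(cand, "error")) {
      errors <- c(errors, conditionMessage(cand))
      next
    }
    if (is.null(best) || cand$reg$residualRMS < best$reg$residualRMS)
      best <- cand
  }
  if (is.null(best))
    stop("symmetry estimation failed for all initial planes: ",
         paste(unique(errors), collapse = "; "))

  aff <- .reflection_affine(best$p0)
  R <- best$reg$transform@rotation
  t <- best$reg$transform@translation
  M <- R %*% aff$H
  cc <- drop(R %*% aff$b) + t
  eg <- eigen(M)
  k <- which.min(abs(Re(eg$values) + 1))
  n <- Re(eg$vectors[, k])
  n <- .canonical_sign(n / sqrt(sum(n^2)))
  d <- sum(n * cc) / 2
  ax <- .inplane_axes(points, n)
  new("SymmetryPlane", plane = Plane(n, d), axisU = ax$u, axisV = ax$v,
      residualRMS = best$reg$residualRMS)
}

#' Serialize / restore a SymmetryPlane as JSON
#'
#' @param s a [SymmetryPlane-class].
#' @param path output (input) file path.
#' @return `writeSymmetryPlane`: invisibly `path`; `readSymmetryPlane`: the
#'   restored [SymmetryPlane-class].
#' @export
writeSymmetryPlane <- function(s, path) {
  stopifnot(is(s, "SymmetryPlane"))
  jsonlite::write_json(
    list(normal = s@plane@normal, offset = s@plane@offset, axisU = s@axisU,
         axisV = s@axisV, residualRMS = s@residualRMS),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeSymmetryPlane
#' @export
readSymmetryPlane <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SymmetryPlane", plane = Plane(x$normal, x$offset),
      axisU = x$axisU, axisV = x$axisV, residualRMS = x$residualRMS)
}
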
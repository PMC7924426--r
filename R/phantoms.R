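#' Phantom classes
#'
#' The four organ classes emulated by the phantom generator.
#' @export
PHANTOM_CLASSES <- c("head", "thorax", "breast", "abdomen")

# intensity tiers: background, organ, bright artifact
.TIER <- c(low = 5, mid = 120, high = 250)

#' Generate a synthetic organ phantom with a known symmetry plane
#'
#' Builds a class-distinctive, approximately bilaterally symmetric 3D
#' volume on an anisotropic grid with three intensity tiers: background
#' (~5), soft-tissue organ structures (~110-135, the band the segmentation
#' should isolate), and bright skeletal structures (~250, the
#' high-intensity extreme the band excludes, as bone is in CT), plus trace
#' bright/dark artifact specks at both histogram extremes, additive
#' Gaussian noise, and an optional mirror-breaking jitter of the lateral
#' structures. Geometry per class:
#' \describe{
#'   \item{head}{large ellipsoid with a bright skull shell, a central dark
#'     cavity, mirrored eye cavities and a brainstem column.}
#'   \item{thorax}{body ellipsoid with two mirrored low-intensity lungs, a
#'     diaphragm dome, heart/trachea cavities and a bright spine column.}
#'   \item{breast}{chest-wall slab with two mirrored hemispheres and a
#'     bright rib plate.}
#'   \item{abdomen}{broad ellipsoid with mirrored kidney blobs, stomach
#'     cavity, bladder blob and a bright spine column.}
#' }
#' The phantom is mirror-symmetric about the plane `x = (n_x - 1)/2` (voxel
#' units); because isotropic resampling leaves the x axis unchanged, the
#' same plane is the ground truth in the resampled frame.
#'
#' @param class one of `"head"`, `"thorax"`, `"breast"`, `"abdomen"`.
#' @param gridShape integer length-3 array size (default `c(96, 96, 40)`).
#' @param spacing physical spacing in mm (default `c(0.8, 0.8, 2.4)`,
#'   anisotropic so that isotropic resampling is exercised).
#' @param noiseSD additive Gaussian noise SD (default 4; tier gaps are ~100).
#' @param asymmetryJitter SD (voxels) of the mirror-breaking displacement of
#'   lateral structures (default 0.5).
#' @param scaleJitter relative SD of per-phantom size variation (default
#'   0.06), giving moderate in-class variability.
#' @param seed RNG seed.
#' @return `list(volume = VolumeGrid, truePlane = Plane, class = class)`.
#' @examples
#' ph <- generatePhantom("head", seed = 1)
#' ph$truePlane
#' @export
generatePhantom <- function(class = PHANTOM_CLASSES,
                            gridShape = c(96L, 96L, 40L),
                            spacing = c(0.8, 0.8, 2.4),
                            noiseSD = 4, asymmetryJitter = 0.5,
                            scaleJitter = 0.06, seed = 1L) {
  class <- match.arg(class)
  stopifnot(noiseSD >= 0, asymmetryJitter >= 0)
  d <- as.integer(gridShape)
  if (any(d < 10L))
    stop("grid too small to contain the phantom geometry (need >= 10 voxels ",
         "per axis)")
  set.seed(seed)
  # physical coordinates of voxel centres, centred on the volume middle
  ext <- (d - 1) * spacing
  xs <- seq(0, ext[1], length.out = d[1]) - ext[1] / 2
  ys <- seq(0, ext[2], length.out = d[2]) - ext[2] / 2
  zs <- seq(0, ext[3], length.out = d[3]) - ext[3] / 2
  # half-extents available, in mm
  hx <- ext[1] / 2; hy <- ext[2] / 2; hz <- ext[3] / 2
  sc <- exp(stats::rnorm(1, 0, scaleJitter))          # per-phantom size factor
  shift_y <- stats::rnorm(1, 0, 0.04) * hy            # in-class position shift
  shift_z <- stats::rnorm(1, 0, 0.04) * hz
  jit <- function() stats::rnorm(3, 0, asymmetryJitter) * spacing[1]

  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  Yc <- Y - shift_y
  Zc <- Z - shift_z
  vol <- array(.TIER["low"], d)

  ell <- function(cx, cy, cz, rx, ry, rz)
    ((X - cx) / rx)^2 + ((Yc - cy) / ry)^2 + ((Zc - cz) / rz)^2 <= 1
  # a lateral structure and its exact mirror, each jittered independently
  mirrored <- function(cx, cy, cz, rx, ry, rz) {
    j1 <- jit(); j2 <- jit()
    ell(cx + j1[1], cy + j1[2], cz + j1[3], rx, ry, rz) |
      ell(-cx + j2[1], cy + j2[2], cz + j2[3], rx, ry, rz)
  }

  # every class carries sizable organ-band structures that are strongly
  # asymmetric along y and z (while exactly mirrored in x), so the x
  # mid-plane is the unique best symmetry plane rather than one of several
  if (class == "head") {
    r <- sc * c(0.78 * hx, 0.88 * hy, 0.88 * hz)
    inner <- ell(0, 0, 0, 0.88 * r[1], 0.88 * r[2], 0.88 * r[3])
    outer <- ell(0, 0, 0, r[1], r[2], r[3])
    vol[outer] <- .TIER["high"]                        # skull shell (bright)
    vol[inner] <- 120                                  # brain tissue
    vol[ell(0, 0.18 * r[2], 0.3 * r[3], 0.18 * r[1], 0.2 * r[2],
            0.26 * r[3])] <- .TIER["low"]              # central cavity (top)
    vol[mirrored(0.38 * r[1], -0.5 * r[2], 0.1 * r[3], 0.15 * r[1],
                 0.14 * r[2], 0.15 * r[3])] <- .TIER["low"]  # eye cavities
    vol[(X / (0.2 * r[1]))^2 + ((Yc - 0.2 * r[2]) / (0.22 * r[2]))^2 <= 1 &
          Zc >= -r[3] & Zc <= -0.3 * r[3]] <- 128      # brainstem (bottom)
    vol[ell(0, -0.45 * r[2], -0.55 * r[3], 0.3 * r[1], 0.34 * r[2],
            0.34 * r[3])] <- .TIER["low"]              # sinus cavity (front)
  } else if (class == "thorax") {
    r <- sc * c(0.9 * hx, 0.72 * hy, 0.9 * hz)
    vol[ell(0, 0, 0, r[1], r[2], r[3])] <- 125         # body
    vol[mirrored(0.42 * r[1], -0.08 * hy, 0.12 * hz, 0.34 * r[1],
                 0.5 * r[2], 0.55 * r[3])] <- .TIER["low"]   # lungs (upper)
    dome <- ell(0, 0, -0.5 * r[3], 0.62 * r[1], 0.55 * r[2], 0.4 * r[3]) &
      Zc < -0.3 * r[3]
    vol[dome] <- 118                                   # diaphragm dome
    vol[(X / (0.14 * r[1]))^2 + ((Yc - 0.35 * r[2]) / (0.22 * r[2]))^2 <= 1 &
          abs(Zc) <= 0.85 * r[3]] <- .TIER["high"]     # spine column (bright)
    vol[ell(0, -0.25 * r[2], 0.1 * r[3], 0.2 * r[1], 0.32 * r[2],
            0.26 * r[3])] <- .TIER["low"]              # heart-like cavity
    vol[(X / (0.09 * r[1]))^2 + ((Yc + 0.05 * r[2]) / (0.12 * r[2]))^2 <= 1 &
          Zc >= 0.35 * r[3] & Zc <= r[3]] <- .TIER["low"]  # trachea (upper)
  } else if (class == "breast") {
    slab <- abs(Yc - 0.3 * hy) <= sc * 0.22 * hy & abs(X) <= 0.85 * hx &
      Zc >= -0.55 * hz & Zc <= 0.8 * hz                # chest-wall slab
    vol[slab] <- 115
    vol[abs(Yc - 0.62 * hy) <= 0.08 * hy & abs(X) <= 0.85 * hx &
          Zc >= -0.55 * hz & Zc <= 0.8 * hz] <- .TIER["high"]  # rib plate
    rr <- sc * 0.42 * min(hx, hz)
    j1 <- jit(); j2 <- jit()
    hemi <- function(cx, j) {
      ((X - cx - j[1]) / rr)^2 + ((Yc + 0.08 * hy - j[2]) / (1.3 * rr))^2 +
        ((Zc - 0.08 * hz - j[3]) / rr)^2 <= 1 & (Yc - j[2]) <= 0.12 * hy
    }
    vol[hemi(0.45 * hx, j1) | hemi(-0.45 * hx, j2)] <- 122
  } else {                                             # abdomen
    r <- sc * c(0.92 * hx, 0.6 * hy, 0.92 * hz)
    vol[ell(0, 0, 0, r[1], r[2], r[3])] <- 115         # broad ellipsoid
    vol[mirrored(0.5 * r[1], 0.25 * r[2], -0.15 * r[3], 0.2 * r[1],
                 0.3 * r[2], 0.3 * r[3])] <- 132       # kidney-like blobs
    vol[(X / (0.17 * r[1]))^2 + ((Yc - 0.38 * r[2]) / (0.32 * r[2]))^2 <= 1 &
          abs(Zc) <= 0.85 * r[3]] <- .TIER["high"]     # spine (bright)
    vol[ell(0, -0.18 * r[2], -0.62 * r[3], 0.28 * r[1], 0.3 * r[2],
            0.26 * r[3])] <- 134                       # bladder-like blob
    vol[ell(0, -0.12 * r[2], 0.3 * r[3], 0.36 * r[1], 0.38 * r[2],
            0.32 * r[3])] <- .TIER["low"]              # stomach-like cavity
  }

  # artifact specks at both histogram extremes (~0.2% of voxels each),
  # placed mirror-symmetrically so noiseless phantoms stay exactly symmetric
  nvox <- prod(d)
  nspeck <- max(1L, round(0.002 * nvox))
  speck <- function(value) {
    idx <- arrayInd(sample.int(nvox, nspeck), d)
    vol[idx] <<- value
    idx[, 1] <- d[1] + 1L - idx[, 1]
    vol[idx] <<- value
  }
  speck(.TIER["high"])
  speck(0)
  if (noiseSD > 0)
    vol <- vol + stats::rnorm(nvox, 0, noiseSD)

  list(volume = VolumeGrid(vol, spacing = spacing),
       truePlane = Plane(c(1, 0, 0), (d[1] - 1) / 2),
       class = class)
}

#' Generate a balanced phantom cohort
#'
#' @param nPerClass phantoms per class (>= 2).
#' @param classes classes to include (default all four).
#' @param seed master seed; per-item seeds are derived from it.
#' @param ... further arguments passed to [generatePhantom]
#'   (`gridShape`, `spacing`, `noiseSD`, `asymmetryJitter`, ...).
#' @return `list(volumes, labels, truePlanes)`; `volumes` are the raw
#'   anisotropic grids (resample before use in the pipeline).
#' @export
generateCohort <- function(nPerClass, classes = PHANTOM_CLASSES, seed = 1L,
                           ...) {
  stopifnot(nPerClass >= 2)
  set.seed(seed)
  n <- nPerClass * length(classes)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  volumes <- vector("list", n)
  planes <- vector("list", n)
  labels <- factor(rep(classes, each = nPerClass), levels = classes)
  for (i in seq_len(n)) {
    ph <- generatePhantom(as.character(labels[i]), seed = seeds[i], ...)
    volumes[[i]] <- ph$volume
    planes[[i]] <- ph$truePlane
  }
  list(volumes = volumes, labels = labels, truePlanes = planes)
}
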
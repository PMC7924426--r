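axis_frame <- function(d, x0) {
  # SymmetryPlane for the axis-aligned plane x = x0 with axes along y and z
  new("SymmetryPlane", plane = Plane(c(1, 0, 0), x0),
      axisU = c(0, 1, 0), axisV = c(0, 0, 1), residualRMS = 0)
}

test_that("volume-vertex bounds reduce to the volume extents for axis-aligned planes", {
  v <- VolumeGrid(array(0, c(20, 20, 20)), spacing = c(1, 1, 1))
  f <- buildFrame(v, axis_frame(dim(v), 10), points = NULL)
  expect_equal(diff(f@uRange), 19)   # y extent of voxel centres
  expect_equal(diff(f@vRange), 19)   # z extent
  expect_equal(f@pixelStep, 19 / 224)

  # doubling the volume doubles both ranges
  v2 <- VolumeGrid(array(0, c(40, 40, 40)), spacing = c(1, 1, 1))
  f2 <- buildFrame(v2, axis_frame(dim(v2), 20), points = NULL)
  expect_equal(diff(f2@uRange), 39)
  expect_equal(diff(f2@vRange), 39)
})

test_that("an axis-aligned frame with unit step reproduces the array slab exactly", {
  set.seed(13)
  v <- VolumeGrid(array(runif(15 * 11 * 9), c(15, 11, 9)), c(1, 1, 1))
  s <- axis_frame(dim(v), 7)    # integer mid-plane x = 7 (0-based)
  f <- buildFrame(v, s, points = NULL)
  f@pixelStep <- 1
  img <- extractPlaneImage(v, f, square = FALSE)
  expect_equal(img, intensities(v)[8, , ], ignore_attr = TRUE)
})

test_that("swapping the frame axes transposes the image", {
  set.seed(14)
  v <- VolumeGrid(array(runif(12 * 12 * 12), c(12, 12, 12)), c(1, 1, 1))
  s <- axis_frame(dim(v), 6)
  f <- buildFrame(v, s, points = NULL)
  f@pixelStep <- 1
  fswap <- new("SliceFrame", origin = f@origin, axisU = f@axisV,
               axisV = f@axisU, uRange = f@vRange, vRange = f@uRange,
               pixelStep = 1)
  expect_equal(extractPlaneImage(v, fswap, square = FALSE),
               t(extractPlaneImage(v, f, square = FALSE)))
})

test_that("samples outside the volume are zero-filled", {
  v <- VolumeGrid(array(1, c(8, 8, 8)), c(1, 1, 1))
  far <- new("SymmetryPlane", plane = Plane(c(1, 0, 0), 100),
             axisU = c(0, 1, 0), axisV = c(0, 0, 1), residualRMS = 0)
  f <- new("SliceFrame", origin = c(100, 3.5, 3.5), axisU = c(0, 1, 0),
           axisV = c(0, 0, 1), uRange = c(-3.5, 3.5), vRange = c(-3.5, 3.5),
           pixelStep = 1)
  expect_true(all(extractPlaneImage(v, f) == 0))
})

test_that("every in-volume sample equals some voxel intensity exactly", {
  set.seed(15)
  vals <- sample(1000:9999, 10 * 10 * 10)   # distinct values
  v <- VolumeGrid(array(vals, c(10, 10, 10)), c(1, 1, 1))
  n <- c(1, 1, 1) / sqrt(3)
  u <- c(1, -1, 0) / sqrt(2)
  s <- new("SymmetryPlane", plane = Plane(n, sum(n * c(4.5, 4.5, 4.5))),
           axisU = u, axisV = SymSlice:::.cross3(n, u), residualRMS = 0)
  f <- buildFrame(v, s, points = NULL)
  img <- extractPlaneImage(v, f)
  expect_true(all(img %in% c(0, vals)))
})

test_that("plane-image extraction is equivariant under rigid motion", {
  v <- make_blob_volume(c(28, 28, 28), sigma = 6)
  # break the blob's symmetry so the image has structure
  a <- intensities(v)
  a[8:12, 8:20, 8:12] <- a[8:12, 8:20, 8:12] + 80
  v <- VolumeGrid(a, c(1, 1, 1))
  s <- axis_frame(dim(v), 13.5)
  f0 <- buildFrame(v, s, points = NULL)
  img0 <- extractPlaneImage(v, f0)

  ang <- c(0, 0, 10)
  res <- applyRigidVolume(v, ang, c(0, 0, 0))
  R <- res$transform@rotation
  t <- res$transform@translation
  s2 <- new("SymmetryPlane",
            plane = Plane(drop(R %*% c(1, 0, 0)),
                          sum((R %*% c(1, 0, 0)) * (R %*% c(13.5, 0, 0) + t))),
            axisU = drop(R %*% c(0, 1, 0)), axisV = drop(R %*% c(0, 0, 1)),
            residualRMS = 0)
  f2 <- buildFrame(res$volume, s2, points = NULL)
  f2@origin <- drop(R %*% f0@origin + t)
  f2@uRange <- f0@uRange
  f2@vRange <- f0@vRange
  f2@pixelStep <- f0@pixelStep
  img2 <- extractPlaneImage(res$volume, f2)
  expect_gte(cor(as.vector(img0), as.vector(img2)), 0.95)
})

test_that("normalization rescales, pads and resizes to 224", {
  m <- matrix(seq(0, 510, length.out = 224 * 224), 224, 224)
  ri <- normalizeImage(m)
  expect_s4_class(ri, "RepresentativeImage")
  expect_identical(dim(pixels(ri)), c(224L, 224L))
  expect_equal(pixels(ri), round(m / 2), tolerance = 1, ignore_attr = TRUE)

  # constant image maps to all zeros
  expect_true(all(pixels(normalizeImage(matrix(37, 50, 50))) == 0))

  # an already-conforming full-range integer image is unchanged
  set.seed(16)
  m2 <- matrix(sample(0:255, 224 * 224, replace = TRUE), 224, 224)
  m2[1] <- 0L; m2[2] <- 255L
  expect_identical(pixels(normalizeImage(m2)), m2)

  # non-square input is padded symmetrically with background before resize
  m3 <- matrix(100, 40, 20)
  px <- pixels(normalizeImage(m3))
  expect_identical(dim(px), c(224L, 224L))
  expect_true(all(px[, 1:40] == 0) && all(px[, 185:224] == 0))

  expect_error(normalizeImage(matrix(numeric(0), 0, 0)), "empty")
})

test_that("representative images write as 8-bit grayscale PNG", {
  set.seed(17)
  ri <- normalizeImage(matrix(runif(224 * 224, 0, 255), 224, 224))
  f <- tempfile(fileext = ".png")
  writeRepresentativeImage(ri, f)
  back <- png::readPNG(f)
  expect_identical(dim(back), c(224L, 224L))
  expect_equal(round(back * 255), pixels(ri), ignore_attr = TRUE)
})

test_that("nccImages finds shifted self-correlation", {
  set.seed(18)
  base <- matrix(0, 64, 64)
  base[20:40, 25:45] <- 1
  base <- base + matrix(rnorm(64 * 64, 0, 0.01), 64, 64)
  shifted <- base[c(4:64, 1:3), c(62:64, 1:61)]   # circular shift 3, -3
  expect_gt(nccImages(base, shifted, maxLag = 6), 0.98)
  expect_equal(nccImages(base, base), 1, tolerance = 1e-9)
})
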
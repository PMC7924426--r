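test_that("isotropic resampling sizes follow the array-size formula", {
  # nz scales by st/ps_x, ny by ps_y/ps_x, nx unchanged
  v <- VolumeGrid(array(rnorm(64 * 64 * 25), c(64, 64, 25)),
                  spacing = c(0.5, 0.5, 2.0))
  expect_identical(dim(resampleIsotropic(v)), c(64L, 64L, 100L))

  v2 <- VolumeGrid(array(rnorm(64 * 50 * 20), c(64, 50, 20)),
                   spacing = c(0.7, 0.7, 3.5))
  expect_identical(dim(resampleIsotropic(v2)), c(64L, 50L, 100L))

  # non-integer sizes round half away from zero: 10 * 1.25 = 12.5 -> 13
  v3 <- VolumeGrid(array(0, c(10, 10, 10)), spacing = c(1, 1.25, 1))
  expect_identical(dim(resampleIsotropic(v3)), c(10L, 13L, 10L))

  out <- resampleIsotropic(v)
  expect_true(isIsotropic(out))
  expect_equal(spacing(out), c(0.5, 0.5, 0.5))
})

test_that("resampling an already-isotropic volume is the identity", {
  v <- VolumeGrid(array(rnorm(10 * 11 * 12), c(10, 11, 12)),
                  spacing = c(1, 1, 1))
  out <- resampleIsotropic(v)
  expect_identical(dim(out), dim(v))
  expect_equal(intensities(out), intensities(v), tolerance = 1e-12)
})

test_that("resampling preserves constants and physical extent", {
  v <- VolumeGrid(array(7.5, c(9, 9, 5)), spacing = c(0.8, 0.8, 2.4))
  out <- resampleIsotropic(v)
  expect_true(all(abs(intensities(out) - 7.5) < 1e-9))

  set.seed(42)
  for (i in 1:20) {
    d <- sample(5:20, 3, replace = TRUE)
    sp <- round(runif(3, 0.3, 3), 2)
    v <- VolumeGrid(array(0, d), spacing = sp)
    out <- resampleIsotropic(v)
    expect_identical(dim(out), pmax(1L, as.integer(floor(d * sp / sp[1] + 0.5))))
    # physical extent preserved within one output voxel per axis
    expect_true(all(abs(dim(out) * sp[1] - d * sp) <= sp[1] + 1e-9))
  }
})

test_that("volume containers round-trip exactly", {
  v <- VolumeGrid(array(rnorm(6 * 7 * 8), c(6, 7, 8)),
                  spacing = c(0.9, 1.1, 2.2))
  rds <- tempfile(fileext = ".rds")
  writeVolume(v, rds, "rds")
  back <- readVolume(rds, "rds")
  expect_identical(intensities(back), intensities(v))
  expect_identical(spacing(back), spacing(v))

  nii <- tempfile(fileext = ".nii.gz")
  writeVolume(v, nii, "nifti")
  back2 <- readVolume(nii, "nifti")
  expect_equal(intensities(back2), intensities(v), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(spacing(back2), spacing(v), tolerance = 1e-6)
  expect_true(isIsotropic(readVolume(writeVolume(
    VolumeGrid(array(0, c(4, 4, 4)), c(1, 1, 1)),
    tempfile(fileext = ".nii.gz"), "nifti"), "nifti")))

  bad <- tempfile()
  writeLines("not a volume", bad)
  suppressWarnings(expect_error(readVolume(bad, "nifti"), "format error"))
  expect_error(readVolume(tempfile(), "rds"), "no such file")
})

test_that("DICOM series round-trips and stacks by InstanceNumber", {
  set.seed(7)
  v <- VolumeGrid(array(runif(16 * 14 * 6, -50, 200), c(16, 14, 6)),
                  spacing = c(0.6, 0.75, 2.5))
  dir <- tempfile()
  paths <- writeDicomSeries(v, dir)
  expect_length(paths, 6)

  # rename so on-disk (lexicographic) order disagrees with InstanceNumber
  shuffled <- file.path(dir, sprintf("z_%02d.dcm", rev(seq_along(paths))))
  file.rename(paths, shuffled)

  rt <- readDicomSeries(dir)
  expect_s4_class(rt$volume, "VolumeGrid")
  expect_identical(dim(rt$volume), dim(v))
  expect_equal(spacing(rt$volume), spacing(v), tolerance = 1e-9)
  expect_identical(rt$meta@instanceNumbers, 1:6)
  # 16-bit quantization via RescaleSlope/Intercept
  tol <- diff(range(intensities(v))) / 65535
  expect_true(max(abs(intensities(rt$volume) - intensities(v))) <= tol + 1e-9)
  expect_false(isIsotropic(rt$volume))
})

test_that("DICOM reader rejects malformed series", {
  v <- VolumeGrid(array(1:(4 * 4 * 3), c(4, 4, 3)), spacing = c(1, 1, 2))

  # a single slice cannot form a volume
  d1 <- tempfile()
  p <- writeDicomSeries(v, d1)
  file.remove(p[2:3])
  expect_error(readDicomSeries(d1), "at least 2")

  # duplicate InstanceNumber
  d2 <- tempfile()
  p <- writeDicomSeries(v, d2)
  file.copy(p[1], file.path(d2, "dup.dcm"))
  expect_error(readDicomSeries(d2), "duplicate InstanceNumber")

  # inconsistent in-plane dimensions
  d3 <- tempfile()
  writeDicomSeries(v, d3)
  writeDicomSeries(VolumeGrid(array(0, c(5, 4, 1)), c(1, 1, 2)), d3,
                   prefix = "other")
  expect_error(readDicomSeries(d3), "shape error")
})

test_that("missing required DICOM tags are reported by name", {
  px <- writeBin(as.integer(matrix(1:16, 4, 4)), raw(), size = 2,
                 endian = "little")
  base <- list(
    list(group = 0x0020, element = 0x0013, vr = "IS", value = "1"),
    list(group = 0x0028, element = 0x0010, vr = "US", value = 4L),
    list(group = 0x0028, element = 0x0011, vr = "US", value = 4L),
    list(group = 0x0028, element = 0x0030, vr = "DS", value = "1\\1"),
    list(group = 0x0028, element = 0x0100, vr = "US", value = 16L),
    list(group = 0x7FE0, element = 0x0010, vr = "OW", value = px))
  thick <- list(group = 0x0018, element = 0x0050, vr = "DS", value = "2")

  dir <- tempfile()
  dir.create(dir)
  SymSlice:::.dicomWriteFile(file.path(dir, "a.dcm"),
                             append(base, list(thick), after = 0))
  SymSlice:::.dicomWriteFile(file.path(dir, "b.dcm"), {
    b <- base
    b[[1]]$value <- "2"
    b            # SliceThickness deliberately absent
  })
  expect_error(readDicomSeries(dir), "SliceThickness")

  dir2 <- tempfile()
  dir.create(dir2)
  for (i in 1:2)
    SymSlice:::.dicomWriteFile(
      file.path(dir2, paste0(i, ".dcm")),
      append(base[-1], list(thick)))  # InstanceNumber absent
  expect_error(readDicomSeries(dir2), "InstanceNumber")

  # not DICOM at all
  dir3 <- tempfile()
  dir.create(dir3)
  writeLines(c("x", "y"), file.path(dir3, "1.dcm"))
  writeLines(c("x", "y"), file.path(dir3, "2.dcm"))
  expect_error(readDicomSeries(dir3), "DICM")
})

test_that("point clouds are written as xyz and PLY", {
  pts <- matrix(rnorm(30), ncol = 3)
  f1 <- tempfile(fileext = ".xyz")
  writePointCloud(pts, f1, "xyz")
  expect_equal(unname(as.matrix(read.table(f1))), pts, tolerance = 1e-6)
  f2 <- tempfile(fileext = ".ply")
  writePointCloud(pts, f2, "ply")
  head <- readLines(f2, n = 3)
  expect_identical(head[1], "ply")
  expect_match(head[3], "element vertex 10")
})
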
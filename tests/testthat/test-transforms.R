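test_that("zero-range perturbation is the identity and draws are reproducible", {
  v <- make_blob_volume(c(16, 16, 16))
  r <- randomRigidVolume(v, PerturbationSpec(0, 0, seed = 1))
  expect_equal(intensities(r$volume), intensities(v), tolerance = 1e-9)
  expect_equal(r$transform@rotation, diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)

  a <- randomRigidVolume(v, PerturbationSpec(15, 5, seed = 9))
  b <- randomRigidVolume(v, PerturbationSpec(15, 5, seed = 9))
  expect_identical(intensities(a$volume), intensities(b$volume))
  expect_identical(a$angles, b$angles)
  c2 <- randomRigidVolume(v, PerturbationSpec(15, 5, seed = 10))
  expect_false(identical(a$angles, c2$angles))
})

test_that("a rigid transform composed with its inverse restores the interior", {
  v <- make_blob_volume(c(24, 24, 24), sigma = 6)
  ang <- c(0, 0, 12)
  off <- c(2.5, -1.5, 1)
  fwd <- applyRigidVolume(v, ang, off)
  Rinv <- t(rotationMatrix(ang))
  back <- applyRigidVolume(fwd$volume, -ang, drop(-Rinv %*% off))
  inner <- 7:18
  orig <- intensities(v)[inner, inner, inner]
  rest <- intensities(back$volume)[inner, inner, inner]
  expect_gt(cor(as.vector(orig), as.vector(rest)), 0.999)
  expect_lt(mean(abs(orig - rest)), 0.5)
})

test_that("axis swaps are exact permutations", {
  set.seed(19)
  v <- VolumeGrid(array(runif(6 * 7 * 8), c(6, 7, 8)), c(1, 1, 1))

  # the 3-cycle applied three times is the identity
  p <- c(2L, 3L, 1L)
  out <- v
  for (i in 1:3) out <- randomAxisSwap(out, perm = p)$volume
  expect_identical(intensities(out), intensities(v))

  # shape permutes accordingly and intensities are conserved as a multiset
  sw <- randomAxisSwap(v, perm = c(3L, 1L, 2L))
  expect_identical(dim(sw$volume), dim(v)[c(3, 1, 2)])
  expect_identical(sort(as.vector(intensities(sw$volume))),
                   sort(as.vector(intensities(v))))

  # random draws avoid the identity and are seed-reproducible
  perms <- vapply(1:50, function(i)
    paste(randomAxisSwap(v, seed = i)$permutation, collapse = ""),
    character(1))
  expect_false(any(perms == "123"))
  expect_identical(randomAxisSwap(v, seed = 3)$permutation,
                   randomAxisSwap(v, seed = 3)$permutation)
})

test_that("perturbation draws respect the configured bounds", {
  v <- VolumeGrid(array(0, c(4, 4, 4)), c(1, 1, 1))
  angs <- offs <- matrix(0, 1000, 3)
  for (i in 1:1000) {
    r <- randomRigidVolume(v, PerturbationSpec(15, 5, seed = i))
    angs[i, ] <- r$angles
    offs[i, ] <- r$offsets
  }
  expect_true(all(abs(angs) <= 15))
  expect_true(all(abs(offs) <= 5))
  # draws actually use the range
  expect_gt(max(abs(angs)), 13)
  expect_gt(max(abs(offs)), 4.5)
})

test_that("dataset splits stratify 70/30 and derive perturbed sets 1:1", {
  # spec-scale counting uses placeholder volumes (split logic never reads them)
  vols <- as.list(seq_len(2400))
  labels <- rep(c("head", "thorax", "breast", "abdomen"), each = 600)
  sp <- buildDatasets(vols, labels, trainFraction = 0.7,
                      spec = PerturbationSpec(seed = 4))
  expect_length(sp@trainIdx, 1680)
  expect_length(sp@testIdx, 720)
  tab <- table(sp@labels[sp@trainIdx])
  expect_true(all(tab == 420))
  expect_true(all(table(sp@labels[sp@testIdx]) == 180))
  # train/test disjoint by construction
  expect_length(intersect(sp@trainIdx, sp@testIdx), 0)
  # augmentation kinds split 50/50
  expect_equal(sum(sp@augmentKind == "swap"), 840)
  expect_equal(sum(sp@augmentKind == "rigid"), 840)

  # determinism
  sp2 <- buildDatasets(vols, labels, trainFraction = 0.7,
                       spec = PerturbationSpec(seed = 4))
  expect_identical(sp@trainIdx, sp2@trainIdx)
  expect_identical(sp@itemSeeds, sp2@itemSeeds)

  # stratification within one item of the target for awkward sizes
  sp3 <- buildDatasets(as.list(1:22), rep(c("a", "b"), c(9, 13)),
                       trainFraction = 0.7)
  expect_equal(as.integer(table(sp3@labels[sp3@trainIdx])), c(6L, 9L))

  expect_error(buildDatasets(vols, labels, trainFraction = 1.0), "between")
  expect_error(buildDatasets(as.list(1:3), c("a", "a", "b")), "2 volumes")
})

test_that("split sets materialize with matching labels and real perturbations", {
  co <- generateCohort(3, classes = c("head", "thorax"), seed = 21,
                       gridShape = c(24L, 24L, 10L))
  iso <- lapply(co$volumes, resampleIsotropic)
  sp <- buildDatasets(iso, co$labels, trainFraction = 0.67,
                      spec = PerturbationSpec(15, 5, seed = 5))
  orig <- splitSet(sp, "test_original")
  trans <- splitSet(sp, "test_transformed")
  swap <- splitSet(sp, "test_axis_swapped")
  expect_identical(orig$labels, trans$labels)
  expect_identical(orig$labels, swap$labels)
  expect_length(trans$volumes, length(orig$volumes))
  for (i in seq_along(orig$volumes)) {
    expect_false(identical(intensities(trans$volumes[[i]]),
                           intensities(orig$volumes[[i]])))
    expect_identical(sort(as.vector(intensities(swap$volumes[[i]]))),
                     sort(as.vector(intensities(orig$volumes[[i]]))))
    expect_identical(trans$records[[i]]$kind, "rigid")
    expect_identical(swap$records[[i]]$kind, "swap")
  }
  aug <- splitSet(sp, "augmented_train")
  expect_identical(aug$labels, splitSet(sp, "train")$labels)
  kinds <- vapply(aug$records, `[[`, character(1), "kind")
  expect_identical(as.integer(sort(table(kinds))), c(2L, 2L))

  f <- tempfile(fileext = ".csv")
  man <- writeSplitManifest(sp, f)
  expect_true(file.exists(f))
  expect_identical(nrow(man), length(iso))
})
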
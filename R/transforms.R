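#' Rotation matrix from per-axis angles
#'
#' Rotations are composed in x, y, z order: `R = Rz %*% Ry %*% Rx`.
#'
#' @param anglesDeg length-3 angles in degrees about x, y, z.
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a random rigid perturbation to a volume
#'
#' Draws one rotation angle per axis uniform in the spec's
#' `+/-rotationRangeDeg` and one offset per axis uniform in
#' `+/-translationRange` (isotropic voxels), rotates about the volume
#' centre, translates, and resamples onto the same grid with linear
#' interpolation (outside fill 0).
#'
#' @param v an isotropic [VolumeGrid-class].
#' @param spec a [PerturbationSpec-class]; its `seed` makes the draw
#'   reproducible.
#' @return `list(volume, transform, angles, offsets)` where `transform` is
#'   the applied [RigidTransform-class] (`x -> R x + t` in voxel
#'   coordinates), kept for ground-truth oracles.
#' @export
randomRigidVolume <- function(v, spec) {
  stopifnot(is(v, "VolumeGrid"), is(spec, "PerturbationSpec"))
  if (!isIsotropic(v)) stop("randomRigidVolume expects an isotropic volume")
  set.seed(spec@seed)
  angles <- stats::runif(3, -spec@rotationRangeDeg, spec@rotationRangeDeg)
  offsets <- stats::runif(3, -spec@translationRange, spec@translationRange)
  applyRigidVolume(v, angles, offsets)
}

#' Apply a given rigid transform to a volume
#'
#' Rotation about the volume centre followed by translation, with linear
#' resampling onto the same grid (fill 0).
#'
#' @param v an isotropic [VolumeGrid-class].
#' @param anglesDeg length-3 rotation angles (degrees, composed x, y, z).
#' @param offsets length-3 translation (voxels).
#' @return `list(volume, transform, angles, offsets)` as in
#'   [randomRigidVolume].
#' @export
applyRigidVolume <- function(v, anglesDeg, offsets) {
  stopifnot(is(v, "VolumeGrid"))
  d <- dim(v@intensities)
  ctr <- (d - 1) / 2
  R <- rotationMatrix(anglesDeg)
  # forward: y = R (x - ctr) + ctr + offsets; resample pulls back
  tfull <- drop(ctr + offsets - R %*% ctr)
  A <- t(R)
  tmap <- drop(ctr - t(R) %*% (ctr + offsets))
  out <- .resampleAffineCpp(v@intensities, as.integer(d), A, tmap,
                            as.integer(d), 1L, 0, FALSE)
  list(volume = VolumeGrid(out, v@spacing),
       transform = RigidTransform(R, tfull),
       angles = anglesDeg, offsets = offsets)
}

.AXIS_PERMS <- list(c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
                    c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Randomly swap the axes of a volume
#'
#' Applies one axis permutation drawn uniformly from the 5 non-identity
#' permutations of (x, y, z) - a pure index permutation (no interpolation),
#' synonymous with 90-degree rotations, simulating a change of imaging
#' direction.
#'
#' @param v an isotropic [VolumeGrid-class].
#' @param seed RNG seed for the draw.
#' @param perm optionally force a specific permutation (length-3 integer);
#'   overrides the random draw.
#' @return `list(volume, permutation)` where new axis `i` is old axis
#'   `permutation[i]`.
#' @export
randomAxisSwap <- function(v, seed = 1L, perm = NULL) {
  stopifnot(is(v, "VolumeGrid"))
  if (!isIsotropic(v)) stop("randomAxisSwap expects an isotropic volume")
  if (is.null(perm)) {
    set.seed(seed)
    perm <- .AXIS_PERMS[[sample.int(5L, 1L)]]
  }
  perm <- as.integer(perm)
  list(volume = VolumeGrid(aperm(v@intensities, perm), v@spacing[perm]),
       permutation = perm)
}

#' Build train/test datasets with derived perturbed test sets
#'
#' Stratified split (default 70/30 by class); the transformed and
#' axis-swapped test sets are derived 1:1 from the original test set, and
#' the augmented training set perturbs each training volume with one of the
#' two perturbation kinds, assigned 50/50 at random. Volumes are perturbed
#' lazily by [splitSet] from per-item seeds derived from `spec@seed`, so the
#' whole construction is reproducible.
#'
#' @param volumes list of isotropic [VolumeGrid-class] objects.
#' @param labels class labels (coerced to factor), one per volume; at least
#'   2 volumes per class.
#' @param trainFraction fraction of each class assigned to training
#'   (default 0.7, strictly between 0 and 1).
#' @param spec a [PerturbationSpec-class].
#' @return a [DatasetSplit-class].
#' @export
buildDatasets <- function(volumes, labels, trainFraction = 0.7,
                          spec = PerturbationSpec()) {
  labels <- factor(labels)
  stopifnot(length(volumes) == length(labels))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be strictly between 0 and 1 ",
         "(test sets must be non-empty)")
  tab <- table(labels)
  if (any(tab < 2))
    stop("split error: every class needs >= 2 volumes; short classes: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  set.seed(spec@seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    ntr <- min(length(idx) - 1L, max(1L, round(length(idx) * trainFraction)))
    train <- c(train, sample(idx, ntr))
  }
  train <- sort(train)
  test <- setdiff(seq_along(volumes), train)
  kind <- rep("rigid", length(train))
  nswap <- length(train) %/% 2L
  kind[sample.int(length(train), nswap)] <- "swap"
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             2L * length(volumes)),
                  ncol = 2L)
  new("DatasetSplit", volumes = volumes, labels = labels,
      trainIdx = as.integer(train), testIdx = as.integer(test),
      augmentKind = kind, spec = spec, itemSeeds = seeds)
}

#' Materialize one set of a DatasetSplit
#'
#' @param split a [DatasetSplit-class].
#' @param which one of `"train"`, `"test_original"`, `"test_transformed"`,
#'   `"test_axis_swapped"`, `"augmented_train"`.
#' @return `list(volumes, labels, records)`; `records` logs the perturbation
#'   applied per item (angles/offsets or permutation), empty for the
#'   unperturbed sets.
#' @export
splitSet <- function(split, which = c("train", "test_original",
                                      "test_transformed", "test_axis_swapped",
                                      "augmented_train")) {
  which <- match.arg(which)
  stopifnot(is(split, "DatasetSplit"))
  sp <- split@spec
  perturb <- function(idx, kinds, seedcol) {
    out <- vector("list", length(idx))
    rec <- vector("list", length(idx))
    for (i in seq_along(idx)) {
      v <- split@volumes[[idx[i]]]
      if (kinds[i] == "rigid") {
        r <- randomRigidVolume(v, PerturbationSpec(sp@rotationRangeDeg,
                                                   sp@translationRange,
                                                   split@itemSeeds[idx[i], seedcol]))
        out[[i]] <- r$volume
        rec[[i]] <- list(kind = "rigid", angles = r$angles,
                         offsets = r$offsets)
      } else {
        r <- randomAxisSwap(v, seed = split@itemSeeds[idx[i], seedcol])
        out[[i]] <- r$volume
        rec[[i]] <- list(kind = "swap", permutation = r$permutation)
      }
    }
    list(volumes = out, records = rec)
  }
  switch(which,
    train = list(volumes = split@volumes[split@trainIdx],
                 labels = split@labels[split@trainIdx], records = list()),
    test_original = list(volumes = split@volumes[split@testIdx],
                         labels = split@labels[split@testIdx],
                         records = list()),
    test_transformed = {
      p <- perturb(split@testIdx, rep("rigid", length(split@testIdx)), 1L)
      list(volumes = p$volumes, labels = split@labels[split@testIdx],
           records = p$records)
    },
    test_axis_swapped = {
      p <- perturb(split@testIdx, rep("swap", length(split@testIdx)), 2L)
      list(volumes = p$volumes, labels = split@labels[split@testIdx],
           records = p$records)
    },
    augmented_train = {
      p <- perturb(split@trainIdx, split@augmentKind, 1L)
      list(volumes = p$volumes, labels = split@labels[split@trainIdx],
           records = p$records)
    })
}

#' Write a DatasetSplit manifest
#'
#' One row per volume with its set membership and, for derived items, the
#' perturbation drawn for it.
#'
#' @param split a [DatasetSplit-class].
#' @param path output CSV path.
#' @return invisibly, the manifest `data.frame`.
#' @export
writeSplitManifest <- function(split, path) {
  stopifnot(is(split, "DatasetSplit"))
  n <- length(split@volumes)
  df <- data.frame(index = seq_len(n), label = as.character(split@labels),
                   set = ifelse(seq_len(n) %in% split@trainIdx, "train",
                                "test"))
  df$augment_kind <- NA_character_
  df$augment_kind[split@trainIdx] <- split@augmentKind
  df$item_seed_rigid <- split@itemSeeds[, 1]
  df$item_seed_swap <- split@itemSeeds[, 2]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
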
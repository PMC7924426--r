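#' Extract the representative slice of a volume
#'
#' Runs the full pre-processing chain: isotropic resampling (skipped when
#' the volume is already isotropic), two-threshold Otsu segmentation,
#' symmetry-plane estimation on the organ point cloud, plane-image
#' extraction (with deterministic orientation canonicalization) and 8-bit
#' normalization.
#'
#' @param v a [VolumeGrid-class] (any spacing).
#' @param bins Otsu histogram bins (default 256).
#' @param maxIter,tol,maxPoints,seed ICP parameters, see [icpRegister].
#' @param rasterSize output image side (default 224).
#' @return `list(image = RepresentativeImage, plane = SymmetryPlane,
#'   thresholds = IntensityThresholds, frame = SliceFrame,
#'   nPoints = cloud size)`.
#' @examples
#' ph <- generatePhantom("thorax", seed = 2)
#' rep <- extractRepresentative(ph$volume)
#' rep$plane
#' @export
extractRepresentative <- function(v, bins = 256L, maxIter = 50L, tol = 1e-4,
                                  maxPoints = 5000L, seed = 1L,
                                  rasterSize = 224L) {
  stopifnot(is(v, "VolumeGrid"))
  iso <- if (isIsotropic(v)) v else resampleIsotropic(v)
  th <- otsuTwoThresholds(iso, bins = bins)
  seg <- segmentBand(iso, th)
  sym <- bestSymmetryPlane(seg$cloud, maxIter = maxIter, tol = tol,
                           maxPoints = maxPoints, seed = seed)
  frame <- buildFrame(iso, sym, rasterSize = rasterSize, points = seg$cloud)
  raw <- extractPlaneImage(iso, frame, square = TRUE, canonicalize = FALSE)
  # resolve the u/-u, v/-v sign ambiguity of the in-plane axes from the
  # cloud's mass balance about the raster centre (equivariant and robust:
  # structure volumes contribute linearly, so the margin is far larger than
  # for moment-based skewness): orient each axis so the heavier side is up
  n <- sym@plane@normal
  rel <- sweep(seg$cloud, 2, sym@plane@offset * n)
  massbal <- function(p) {
    ctr <- mean(stats::quantile(p, c(0.05, 0.95), names = FALSE))
    mean(p > ctr) - mean(p < ctr)
  }
  if (massbal(drop(rel %*% sym@axisU)) < 0) raw <- raw[nrow(raw):1, , drop = FALSE]
  if (massbal(drop(rel %*% sym@axisV)) < 0) raw <- raw[, ncol(raw):1, drop = FALSE]
  list(image = normalizeImage(raw, size = rasterSize), plane = sym,
       thresholds = th, frame = frame, nPoints = nrow(seg$cloud))
}

#' Extract a representative image from a file and write the outputs
#'
#' File-level wrapper over [extractRepresentative]: reads a DICOM series
#' directory or a NIfTI/rds volume, writes the representative image as an
#' 8-bit PNG, the symmetry plane as JSON, and a small stage log.
#'
#' @param input path to a DICOM directory or a volume file.
#' @param outputPrefix prefix for the written files
#'   (`<prefix>.png`, `<prefix>_plane.json`, `<prefix>_log.json`).
#' @param format input format: `"auto"` (directory = DICOM, `.nii`/`.nii.gz`
#'   = NIfTI, otherwise rds), `"dicom"`, `"nifti"`, `"rds"`.
#' @param ... passed to [extractRepresentative].
#' @return invisibly, the paths written.
#' @export
extractToFiles <- function(input, outputPrefix, format = "auto", ...) {
  if (!file.exists(input)) stop("unreadable input path: ", input)
  if (format == "auto")
    format <- if (dir.exists(input)) "dicom"
              else if (grepl("\\.nii(\\.gz)?$", input)) "nifti" else "rds"
  v <- switch(format,
    dicom = readDicomSeries(input)$volume,
    nifti = readVolume(input, "nifti"),
    rds = readVolume(input, "rds"),
    stop("unknown format: ", format))
  t0 <- proc.time()[3]
  res <- extractRepresentative(v, ...)
  paths <- c(png = paste0(outputPrefix, ".png"),
             plane = paste0(outputPrefix, "_plane.json"),
             log = paste0(outputPrefix, "_log.json"))
  writeRepresentativeImage(res$image, paths["png"])
  writeSymmetryPlane(res$plane, paths["plane"])
  jsonlite::write_json(
    list(input = input, thresholds = unname(thresholds(res$thresholds)),
         residual_rms = res$plane@residualRMS, n_points = res$nPoints,
         elapsed_s = unname(proc.time()[3] - t0)),
    paths["log"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Run the scaled orientation-invariance experiment on phantoms
#'
#' Generates a balanced phantom cohort, splits it 70/30 by class, extracts
#' representative slices for every item, trains the classifier on the
#' training representatives and evaluates on the three test conditions
#' (original, randomly rotated/translated, axis-swapped). With
#' `regimes = c("unaugmented", "augmented")` the training is repeated on
#' the perturbed (50% rigid / 50% axis-swap) copy of the training set,
#' reproducing the full 3-condition x 2-regime grid.
#'
#' @param nPerClass phantoms per class (default 30: 21/9 train/test per
#'   class at the default fraction).
#' @param trainFraction train fraction (default 0.7).
#' @param regimes subset of `c("unaugmented", "augmented")`.
#' @param backend `"dcnn"` or `"hogsvm"`.
#' @param epochs,batchSize,lr DCNN training protocol (defaults 20, 16,
#'   1e-3 - the desk-scale protocol).
#' @param spec a [PerturbationSpec-class] (the paper-default +/-15 degree,
#'   +/-5 voxel bounds).
#' @param seed master seed; all stage seeds derive from it.
#' @param outputDir if non-NULL, metric reports (JSON) and confusion
#'   matrices (CSV) are written there.
#' @param phantomArgs list of extra arguments for [generateCohort].
#' @param verbose print progress.
#' @return nested list: `result[[regime]][[condition]]` holds
#'   `list(report = MetricReport, confusion = matrix)`; attribute
#'   `"timings"` carries stage wall times.
#' @export
runExperiment <- function(nPerClass = 30L, trainFraction = 0.7,
                          regimes = "unaugmented",
                          backend = c("dcnn", "hogsvm"), epochs = 20L,
                          batchSize = 16L, lr = 1e-3,
                          spec = PerturbationSpec(15, 5),
                          seed = 1L, outputDir = NULL,
                          phantomArgs = list(), verbose = FALSE) {
  backend <- match.arg(backend)
  regimes <- match.arg(regimes, c("unaugmented", "augmented"),
                       several.ok = TRUE)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  t0 <- proc.time()[3]
  cohort <- do.call(generateCohort,
                    c(list(nPerClass = nPerClass, seed = stage_seeds[1]),
                      phantomArgs))
  iso <- lapply(cohort$volumes, resampleIsotropic)
  split <- buildDatasets(iso, cohort$labels, trainFraction = trainFraction,
                         spec = PerturbationSpec(spec@rotationRangeDeg,
                                                 spec@translationRange,
                                                 stage_seeds[2]))
  t_gen <- proc.time()[3] - t0

  rep_of <- function(vols, tag) {
    out <- vector("list", length(vols))
    for (i in seq_along(vols)) {
      out[[i]] <- extractRepresentative(vols[[i]],
                                        seed = stage_seeds[3])$image
      if (verbose && i %% 20 == 0)
        message(tag, ": ", i, "/", length(vols), " slices extracted")
    }
    out
  }
  t0 <- proc.time()[3]
  sets <- list(train = splitSet(split, "train"))
  conditions <- c(original = "test_original", transformed = "test_transformed",
                  axis_swapped = "test_axis_swapped")
  for (cn in names(conditions)) sets[[cn]] <- splitSet(split, conditions[cn])
  if ("augmented" %in% regimes)
    sets$augmented <- splitSet(split, "augmented_train")
  imgs <- lapply(names(sets), function(nm) rep_of(sets[[nm]]$volumes, nm))
  names(imgs) <- names(sets)
  t_extract <- proc.time()[3] - t0

  evaluate <- function(train_imgs, train_labels) {
    if (backend == "dcnn") {
      model <- buildDcnn(dcnnConfig(numClasses = nlevels(train_labels),
                                    seed = stage_seeds[4]))
      fit <- trainDcnn(model, train_imgs, train_labels, epochs = epochs,
                       batchSize = batchSize, lr = lr,
                       seed = stage_seeds[5], verbose = verbose)
      predict_fun <- function(im) predictDcnn(fit$model, im)$labels
    } else {
      predict_fun <- function(im)
        hogSvmClassify(train_imgs, train_labels, im, seed = stage_seeds[6])
    }
    out <- list()
    for (cn in names(conditions)) {
      pred <- predict_fun(imgs[[cn]])
      cm <- confusionCounts(sets[[cn]]$labels, pred,
                            levels = levels(train_labels))
      out[[cn]] <- list(report = computeMetrics(cm), confusion = cm)
    }
    out
  }

  t0 <- proc.time()[3]
  result <- list()
  if ("unaugmented" %in% regimes)
    result$unaugmented <- evaluate(imgs$train, sets$train$labels)
  if ("augmented" %in% regimes)
    result$augmented <- evaluate(imgs$augmented, sets$augmented$labels)
  t_train <- proc.time()[3] - t0

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    for (rg in names(result)) {
      for (cn in names(result[[rg]])) {
        writeMetricReport(result[[rg]][[cn]]$report,
                          file.path(outputDir,
                                    sprintf("metrics_%s_%s.json", rg, cn)))
        utils::write.csv(result[[rg]][[cn]]$confusion,
                         file.path(outputDir,
                                   sprintf("confusion_%s_%s.csv", rg, cn)))
      }
    }
    writeSplitManifest(split, file.path(outputDir, "split_manifest.csv"))
  }
  attr(result, "timings") <- c(generate = unname(t_gen),
                               extract = unname(t_extract),
                               train_eval = unname(t_train))
  result
}
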
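#' Histogram-of-oriented-gradients descriptor of an image
#'
#' Classic HOG: central-difference gradients, unsigned orientation binned
#' into `bins` orientations with linear interpolation between neighbouring
#' bins, magnitude-weighted votes accumulated over `cell x cell` pixel
#' cells, and L2-normalized `block x block` cell blocks (stride one cell).
#'
#' @param img numeric matrix or [RepresentativeImage-class].
#' @param cell cell side in pixels (default 8).
#' @param bins orientation bins over 0-180 degrees (default 9).
#' @param block block side in cells (default 2).
#' @return numeric descriptor vector.
#' @export
hogFeatures <- function(img, cell = 8L, bins = 9L, block = 2L) {
  if (is(img, "RepresentativeImage")) img <- img@pixels
  img <- as.matrix(img) * 1.0
  nr <- nrow(img)
  nc <- ncol(img)
  gx <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  gy <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  ncell_r <- nr %/% cell
  ncell_c <- nc %/% cell
  keep_r <- seq_len(ncell_r * cell)
  keep_c <- seq_len(ncell_c * cell)
  mag <- mag[keep_r, keep_c]
  ang <- ang[keep_r, keep_c]
  ci <- (keep_r - 1L) %/% cell
  cj <- (keep_c - 1L) %/% cell
  cellIdx <- outer(ci, cj, function(a, b) a + ncell_r * b) + 1L
  ncells <- ncell_r * ncell_c
  binw <- 180 / bins
  pos <- ang / binw - 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  bin_lo <- (b0 %% bins) + 1L
  bin_hi <- ((b0 + 1) %% bins) + 1L
  h <- numeric(ncells * bins)
  acc <- function(bin, w) {
    idx <- as.vector(cellIdx) + ncells * (as.vector(bin) - 1L)
    t <- rowsum(as.vector(mag * w), idx)
    h[as.integer(rownames(t))] <<- h[as.integer(rownames(t))] + t[, 1]
  }
  acc(bin_lo, 1 - w1)
  acc(bin_hi, w1)
  hist <- array(h, c(ncell_r, ncell_c, bins))
  nb_r <- ncell_r - block + 1L
  nb_c <- ncell_c - block + 1L
  out <- numeric(nb_r * nb_c * block * block * bins)
  pos <- 1L
  blen <- block * block * bins
  for (j in seq_len(nb_c)) {
    for (i in seq_len(nb_r)) {
      v <- as.vector(hist[i:(i + block - 1L), j:(j + block - 1L), ])
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) v <- v / nv
      out[pos:(pos + blen - 1L)] <- v
      pos <- pos + blen
    }
  }
  out
}

#' Classify representative images with HOG features and an SVM
#'
#' The conventional-classifier backend: a HOG descriptor per image and a
#' multi-class (one-vs-one) support vector machine whose cost parameter is
#' selected by k-fold cross-validation on the training set.
#'
#' @param trainImages,testImages lists of [RepresentativeImage-class] (or
#'   224x224 matrices).
#' @param trainLabels training class labels (>= 2 classes).
#' @param folds cross-validation folds for hyperparameter selection
#'   (default 5).
#' @param costs candidate SVM cost values.
#' @param seed RNG seed (fold assignment).
#' @return factor of predicted labels for `testImages`.
#' @export
hogSvmClassify <- function(trainImages, trainLabels, testImages, folds = 5L,
                           costs = c(0.01, 0.1, 1, 10), seed = 1L) {
  trainLabels <- factor(trainLabels)
  if (nlevels(droplevels(trainLabels)) < 2L)
    stop("SVM training requires at least 2 classes")
  xtr <- t(vapply(trainImages, hogFeatures, numeric(length(
    hogFeatures(trainImages[[1]])))))
  xte <- t(vapply(testImages, hogFeatures, numeric(ncol(xtr))))
  set.seed(seed)
  tuned <- e1071::tune.svm(x = xtr, y = trainLabels, kernel = "linear",
                           cost = costs, scale = FALSE,
                           tunecontrol = e1071::tune.control(
                             sampling = "cross", cross = folds))
  pred <- stats::predict(tuned$best.model, xte)
  factor(as.character(pred), levels = levels(trainLabels))
}
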
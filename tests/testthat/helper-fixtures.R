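# Shared fixtures and independent oracles, built in code at test time.

# small deterministic random cloud with anisotropic spread (well-posed for
# registration tests)
make_cloud <- function(n = 300, seed = 1, scale = c(10, 6, 3)) {
  set.seed(seed)
  sweep(matrix(rnorm(3 * n), ncol = 3), 2, scale, "*")
}

# a cloud exactly symmetric about the plane x = 0
make_symmetric_cloud <- function(n = 300, seed = 1) {
  half <- make_cloud(n, seed)
  half[, 1] <- abs(half[, 1]) + 0.5
  rbind(half, sweep(half, 2, c(-1, 1, 1), "*"))
}

# independent brute-force oracle: exhaustive within-class-variance
# minimization over all threshold bin pairs of a histogram (plain loops,
# no shared code with the implementation)
otsu_oracle_pair <- function(counts) {
  B <- length(counts)
  mids <- seq_len(B) - 0.5
  best <- c(NA, NA)
  best_val <- Inf
  for (i in 1:(B - 2)) {
    for (j in (i + 1):(B - 1)) {
      groups <- list(1:i, (i + 1):j, (j + 1):B)
      wcv <- 0
      for (g in groups) {
        w <- sum(counts[g])
        if (w > 0) {
          mu <- sum(counts[g] * mids[g]) / w
          wcv <- wcv + sum(counts[g] * (mids[g] - mu)^2)
        }
      }
      if (wcv < best_val) {
        best_val <- wcv
        best <- c(i, j)
      }
    }
  }
  best
}

# histogram binning identical to the segmentation contract: `bins` equal
# bins over [min, max], top bin right-closed
bin_counts_oracle <- function(x, bins) {
  rng <- range(x)
  idx <- pmin(bins, pmax(1, floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1))
  tabulate(idx, nbins = bins)
}

# map an IntensityThresholds back to histogram bin indices
thresholds_to_bins <- function(th, x, bins) {
  rng <- range(x)
  tt <- thresholds(th)
  as.integer(round((tt - rng[1]) / (rng[2] - rng[1]) * bins))
}

# independent one-vs-rest metric computation from a confusion matrix
# (plain loops; macro means for everything except accuracy)
metrics_oracle <- function(cm) {
  K <- nrow(cm)
  total <- sum(cm)
  sens <- spec <- prec <- fm <- gm <- numeric(K)
  for (k in 1:K) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[k] <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    fm[k] <- if (prec[k] + sens[k] > 0)
      2 * prec[k] * sens[k] / (prec[k] + sens[k]) else 0
    gm[k] <- sqrt(sens[k] * spec[k])
  }
  list(accuracy = sum(diag(cm)) / total, sensitivity = mean(sens),
       specificity = mean(spec), precision = mean(prec),
       fMeasure = mean(fm), gMean = mean(gm))
}

# rotation angle (degrees) between two rotation matrices
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  R <- crossprod(R2, R1)
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# angle (degrees) between two directions, ignoring sign
axis_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, ca)) * 180 / pi
}

# small smooth test volume (Gaussian blob), isotropic
make_blob_volume <- function(d = c(24, 24, 24), center = (d - 1) / 2,
                             sigma = 5) {
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  a <- exp(-((g$x - center[1])^2 + (g$y - center[2])^2 +
               (g$z - center[3])^2) / (2 * sigma^2))
  VolumeGrid(array(a * 100, d), spacing = c(1, 1, 1))
}

# tiny phantom arguments for fast unit tests
tiny_phantom <- function(class = "head", seed = 1, ...) {
  generatePhantom(class, gridShape = c(48L, 48L, 20L), seed = seed, ...)
}
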
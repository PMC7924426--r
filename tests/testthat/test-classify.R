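make_two_class_images <- function(n_per_class, size = 32, seed = 1,
                                  noise = 8) {
  # linearly separable by construction: bright patch top-left vs bottom-right
  set.seed(seed)
  imgs <- list()
  labels <- character(0)
  for (i in seq_len(n_per_class)) {
    a <- matrix(pmin(255, pmax(0, rnorm(size^2, 30, noise))), size, size)
    a[3:12, 3:12] <- 220
    b <- matrix(pmin(255, pmax(0, rnorm(size^2, 30, noise))), size, size)
    b[(size - 11):(size - 2), (size - 11):(size - 2)] <- 220
    imgs <- c(imgs, list(round(a), round(b)))
    labels <- c(labels, "A", "B")
  }
  list(images = imgs, labels = factor(labels))
}

test_that("the network has the canonical 20-layer sequence", {
  m <- buildDcnn(dcnnConfig())
  layers <- dcnnLayers(m)
  expect_length(layers, 20)
  expect_identical(layers[1], "imageinput")
  expect_identical(layers[18:20], c("fc", "softmax", "classoutput"))
  types <- sub("[0-9]+$", "", layers)
  expect_identical(as.integer(table(types)[c("conv", "batchnorm", "relu",
                                             "maxpool")]),
                   rep(4L, 4))
  # blocks are ordered conv -> batchnorm -> relu -> maxpool
  expect_identical(types[2:5], c("conv", "batchnorm", "relu", "maxpool"))

  # the dense layer matches the class count
  expect_identical(nrow(m$params$fc$W), 4L)
  m6 <- buildDcnn(dcnnConfig(numClasses = 6))
  expect_identical(nrow(m6$params$fc$W), 6L)

  expect_error(dcnnConfig(filters = c(8, 16)), "4 conv blocks")
  expect_error(dcnnConfig(numClasses = 1), "2 classes")
})

test_that("initialization is deterministic under a fixed seed", {
  m1 <- buildDcnn(dcnnConfig(seed = 5))
  m2 <- buildDcnn(dcnnConfig(seed = 5))
  expect_identical(m1$params, m2$params)
  m3 <- buildDcnn(dcnnConfig(seed = 6))
  expect_false(identical(m1$params$conv1$W, m3$params$conv1$W))
})

test_that("training fits linearly separable images and is reproducible", {
  data <- make_two_class_images(20, size = 32)
  cfg <- dcnnConfig(numClasses = 2, inputSize = 32, filters = c(4, 8, 8, 8),
                    seed = 2)
  # flips off: these classes differ by patch POSITION, which in-plane flips
  # deliberately identify (the augmentation exists to merge such pairs)
  fit <- trainDcnn(buildDcnn(cfg), data$images, data$labels, epochs = 50,
                   batchSize = 8, flipAugment = FALSE, seed = 3)
  expect_equal(max(fit$log$accuracy), 1.0)
  expect_lte(nrow(fit$log), 50)

  # training accuracy reached 1 and predictions memorize the training set
  pred <- predictDcnn(fit$model, data$images)
  expect_gte(mean(pred$labels == data$labels), 0.95)

  # reproducibility: identical loss trajectory under the same seed
  fit2 <- trainDcnn(buildDcnn(cfg), data$images, data$labels, epochs = 5,
                    batchSize = 8, seed = 3)
  fit3 <- trainDcnn(buildDcnn(cfg), data$images, data$labels, epochs = 5,
                    batchSize = 8, seed = 3)
  expect_identical(fit2$log$loss, fit3$log$loss)

  # zero epochs leaves the parameters untouched
  m0 <- buildDcnn(cfg)
  fit0 <- trainDcnn(m0, data$images, data$labels, epochs = 0)
  expect_identical(fit0$model$params, m0$params)

  expect_error(trainDcnn(buildDcnn(cfg), data$images[1:3],
                         factor(c("A", "A", "A"), levels = c("A", "B"))),
               "at least 2 classes")
})

test_that("prediction yields normalized probabilities and consistent labels", {
  data <- make_two_class_images(6, size = 32)
  cfg <- dcnnConfig(numClasses = 2, inputSize = 32, filters = c(2, 4, 4, 4),
                    seed = 1)
  fit <- trainDcnn(buildDcnn(cfg), data$images, data$labels, epochs = 3,
                   batchSize = 4, seed = 1)
  p <- predictDcnn(fit$model, data$images)
  expect_equal(rowSums(p$probabilities), rep(1, length(data$images)),
               tolerance = 1e-6)
  idx <- max.col(p$probabilities)
  expect_identical(as.character(p$labels),
                   colnames(p$probabilities)[idx])
  expect_equal(p$confidence,
               100 * p$probabilities[cbind(seq_len(nrow(p$probabilities)),
                                           idx)],
               tolerance = 1e-9)

  # wrong input shape is a shape error
  expect_error(predictDcnn(fit$model, list(matrix(0, 10, 10))), "shape error")
})

test_that("gradients of every layer match numerical differentiation", {
  set.seed(20)
  cfg <- dcnnConfig(numClasses = 3, inputSize = 16, filters = c(2, 3, 4, 5),
                    seed = 2)
  m <- buildDcnn(cfg)
  x <- array(runif(16 * 16 * 4), c(16, 16, 1, 4))
  onehot <- matrix(0, 3, 4)
  onehot[cbind(c(1L, 2L, 3L, 1L), 1:4)] <- 1
  loss_of <- function(mm)
    -sum(log(SymSlice:::.dcnn_forward(mm, x, TRUE)$probs[onehot > 0])) / 4
  fw <- SymSlice:::.dcnn_forward(m, x, training = TRUE)
  gr <- SymSlice:::.dcnn_backward(fw$model, fw, onehot)
  eps <- 1e-6
  for (ch in list(c("conv1", "W", 5), c("conv3", "W", 17), c("bn2", "gamma", 2),
                  c("bn4", "beta", 3), c("fc", "W", 14), c("fc", "b", 2))) {
    nm <- ch[1]; pn <- ch[2]; i <- as.integer(ch[3])
    m2 <- m; m2$params[[nm]][[pn]][i] <- m2$params[[nm]][[pn]][i] + eps
    m3 <- m; m3$params[[nm]][[pn]][i] <- m3$params[[nm]][[pn]][i] - eps
    num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
    expect_equal(gr[[nm]][[pn]][i], num, tolerance = 1e-5,
                 info = paste(nm, pn))
  }
})

test_that("HOG descriptors capture oriented structure", {
  # vertical step edge: all gradient energy in one orientation
  img <- matrix(0, 224, 224)
  img[, 113:224] <- 255
  h <- hogFeatures(img)
  expect_length(h, 27 * 27 * 4 * 9)
  # per block: 4 cells x 9 bins, cells fastest within each bin
  blocks <- matrix(h, nrow = 36)
  active <- blocks[, colSums(blocks) > 0, drop = FALSE]
  bin_energy <- apply(active, 2, function(v) colSums(matrix(v, nrow = 4)))
  share <- apply(bin_energy, 2, function(e) max(e) / sum(e))
  # each active block is dominated by a single orientation bin
  expect_gt(min(share), 0.9)

  # constant image: zero descriptor
  expect_true(all(hogFeatures(matrix(5, 224, 224)) == 0))
})

test_that("HOG+SVM memorizes separable classes and degrades to chance on noise", {
  data <- make_two_class_images(8, size = 224, noise = 4)
  pred <- hogSvmClassify(data$images, data$labels, data$images, folds = 3)
  expect_equal(mean(pred == data$labels), 1.0)

  # constant images carry no signal: accuracy near chance
  flat <- lapply(1:16, function(i) matrix(128, 224, 224))
  pred2 <- hogSvmClassify(flat, factor(rep(c("A", "B"), 8)), flat, folds = 3)
  expect_lte(mean(pred2 == rep(c("A", "B"), 8)), 0.6)

  expect_error(hogSvmClassify(data$images[1:2], factor(c("A", "A")),
                              data$images[1:2]),
               "at least 2 classes")
})
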
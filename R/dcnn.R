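# Compact 20-layer CNN: image input, 4 x (conv 3x3 same / batch norm / ReLU
# / max-pool 2x2 stride 2), fully connected, softmax, class output.
# Convolution and pooling run through RcppArmadillo kernels; batch norm, the
# dense layer and SGD live here.

#' DcnnConfig: architecture of the 20-layer classification network
#'
#' @slot numClasses number of output classes.
#' @slot inputSize input side length (square single-channel images;
#'   default 224).
#' @slot filters integer length-4, filters per conv block (default
#'   `c(8, 16, 32, 64)`, a conventional doubling schedule taking 224 down
#'   to a 14x14 feature map).
#' @slot kernel odd conv kernel size (default 3).
#' @slot seed initialization seed.
#' @export
setClass("DcnnConfig",
  representation(numClasses = "integer", inputSize = "integer",
                 filters = "integer", kernel = "integer", seed = "integer"))

setValidity("DcnnConfig", function(object) {
  if (length(object@filters) != 4L)
    return("exactly 4 conv blocks are required (20-layer architecture)")
  if (object@kernel %% 2L != 1L) return("kernel must be odd")
  if (object@numClasses < 2L) return("need at least 2 classes")
  if (object@inputSize < 16L) return("inputSize must be >= 16")
  TRUE
})

#' @rdname DcnnConfig-class
#' @param numClasses,inputSize,filters,kernel,seed see slots.
#' @return a [DcnnConfig-class].
#' @export
dcnnConfig <- function(numClasses = 4L, inputSize = 224L,
                       filters = c(8L, 16L, 32L, 64L), kernel = 3L,
                       seed = 1L) {
  new("DcnnConfig", numClasses = as.integer(numClasses),
      inputSize = as.integer(inputSize), filters = as.integer(filters),
      kernel = as.integer(kernel), seed = as.integer(seed))
}

#' Build the 20-layer network
#'
#' Initializes all parameters deterministically from `cfg@seed` (He-scaled
#' Gaussians for conv and dense weights; batch-norm scale 1, shift 0).
#'
#' @param cfg a [DcnnConfig-class].
#' @return a model handle (list) for [trainDcnn] / [predictDcnn];
#'   `model$layers` holds the 20 layer types in order.
#' @export
buildDcnn <- function(cfg) {
  stopifnot(is(cfg, "DcnnConfig"))
  set.seed(cfg@seed)
  k <- cfg@kernel
  chans <- c(1L, cfg@filters)
  size <- cfg@inputSize
  params <- list()
  for (b in 1:4) {
    fan_in <- k * k * chans[b]
    params[[paste0("conv", b)]] <- list(
      W = matrix(stats::rnorm(fan_in * chans[b + 1], 0, sqrt(2 / fan_in)),
                 fan_in, chans[b + 1]),
      b = numeric(chans[b + 1]))
    params[[paste0("bn", b)]] <- list(
      gamma = rep(1, chans[b + 1]), beta = numeric(chans[b + 1]),
      runMean = numeric(chans[b + 1]), runVar = rep(1, chans[b + 1]))
    size <- size %/% 2L
  }
  feat <- size * size * cfg@filters[4]
  params$fc <- list(
    W = matrix(stats::rnorm(cfg@numClasses * feat, 0, sqrt(2 / feat)),
               cfg@numClasses, feat),
    b = numeric(cfg@numClasses))
  layers <- c("imageinput",
              as.vector(rbind(paste0("conv", 1:4), paste0("batchnorm", 1:4),
                              paste0("relu", 1:4), paste0("maxpool", 1:4))),
              "fc", "softmax", "classoutput")
  list(cfg = cfg, params = params, layers = layers, featSize = size,
       classes = NULL, trained = FALSE)
}

#' Layer-type sequence of a model
#'
#' @param model a model from [buildDcnn].
#' @return character vector of the 20 layer names in order.
#' @export
dcnnLayers <- function(model) model$layers

# per-channel sums of a (H,W,C,N) array -> length-C vector
.ch_sum <- function(x, d) {
  m <- matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
  rowSums(m)
}

# broadcast a per-channel vector over a (H,W,C,N) array (as a plain vector)
.ch_rep <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

.bn_fw <- function(x, p, training, eps = 1e-5, rho = 0.9) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- .ch_sum(x, d) / m
    vv <- .ch_sum(x * x, d) / m - mu^2
    vv <- pmax(vv, 0)
    p$runMean <- rho * p$runMean + (1 - rho) * mu
    p$runVar <- rho * p$runVar + (1 - rho) * vv
  } else {
    mu <- p$runMean
    vv <- p$runVar
  }
  inv <- 1 / sqrt(vv + eps)
  xhat <- (x - .ch_rep(mu, d)) * .ch_rep(inv, d)
  y <- xhat * .ch_rep(p$gamma, d) + .ch_rep(p$beta, d)
  dim(xhat) <- d
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, p = p)
}

.bn_bw <- function(cache, p, dy) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  dgamma <- .ch_sum(dy * cache$xhat, d)
  dbeta <- .ch_sum(dy, d)
  dxhat <- dy * .ch_rep(p$gamma, d)
  s1 <- .ch_rep(.ch_sum(dxhat, d), d)
  s2 <- .ch_rep(.ch_sum(dxhat * cache$xhat, d), d)
  dx <- (.ch_rep(cache$inv, d) / m) * (m * dxhat - s1 - cache$xhat * s2)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.dcnn_forward <- function(model, x, training) {
  k <- model$cfg@kernel
  p <- model$params
  caches <- list()
  for (b in 1:4) {
    cname <- paste0("conv", b)
    bname <- paste0("bn", b)
    z <- .convFwCpp(x, p[[cname]]$W, p[[cname]]$b, k)
    bn <- .bn_fw(z, p[[bname]], training)
    p[[bname]] <- bn$p
    r <- pmax(bn$y, 0)
    dim(r) <- dim(bn$y)
    mp <- .maxpoolFwCpp(r)
    caches[[b]] <- list(x = x, z = z, bn = bn, relu_in = bn$y,
                        argmax = mp$argmax, relu_dim = dim(r))
    x <- mp$y
  }
  d <- dim(x)
  feat <- matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
  logits <- p$fc$W %*% feat + p$fc$b
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  probs <- sweep(e, 2, colSums(e), "/")
  model$params <- p
  list(model = model, probs = probs, feat = feat, featDim = d,
       caches = caches)
}

.dcnn_backward <- function(model, fw, onehot) {
  p <- model$params
  k <- model$cfg@kernel
  n <- ncol(onehot)
  grads <- list()
  dlogits <- (fw$probs - onehot) / n
  grads$fc <- list(W = dlogits %*% t(fw$feat), b = rowSums(dlogits))
  dfeat <- t(p$fc$W) %*% dlogits
  dx <- array(dfeat, fw$featDim)
  for (b in 4:1) {
    cache <- fw$caches[[b]]
    dr <- .maxpoolBwCpp(cache$argmax, dx, as.integer(cache$relu_dim))
    dr <- dr * (cache$relu_in > 0)
    dim(dr) <- cache$relu_dim
    bnb <- .bn_bw(cache$bn, p[[paste0("bn", b)]], dr)
    grads[[paste0("bn", b)]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cb <- .convBwCpp(cache$x, p[[paste0("conv", b)]]$W, bnb$dx, k)
    grads[[paste0("conv", b)]] <- list(W = cb$dw, b = cb$db)
    dx <- cb$dx
  }
  grads
}

.images_to_array <- function(images, size) {
  n <- length(images)
  x <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) {
    m <- if (is(images[[i]], "RepresentativeImage")) images[[i]]@pixels
         else images[[i]]
    if (!all(dim(m) == c(size, size)))
      stop("shape error: image ", i, " is ", paste(dim(m), collapse = "x"),
           ", expected ", size, "x", size)
    x[, , 1L, i] <- m / 255
  }
  x
}

#' Train the network with SGD
#'
#' Minimizes the cross-entropy over mini-batches with momentum SGD. With
#' `flipAugment = TRUE` each image is randomly flipped along the in-plane
#' axes each epoch (probability 1/2 per axis), absorbing the residual
#' orientation sign ambiguity of the representative slice. Fully
#' reproducible under a fixed `seed`.
#'
#' @param model a model from [buildDcnn].
#' @param images list of [RepresentativeImage-class] (or matrices matching
#'   the configured input size).
#' @param labels class labels (factor; at least 2 classes present; the
#'   number of levels must equal the configured class count).
#' @param epochs training epochs (default 30; 0 returns the model
#'   unchanged).
#' @param batchSize mini-batch size (default 32).
#' @param lr,momentum SGD learning rate and momentum (defaults 1e-3, 0.9).
#' @param flipAugment random in-plane flip augmentation (default TRUE).
#' @param seed RNG seed for shuffling/flips.
#' @param verbose print per-epoch loss/accuracy.
#' @return `list(model, log)`; `log` is a data.frame with per-epoch mean
#'   loss and training accuracy.
#' @export
trainDcnn <- function(model, images, labels, epochs = 30L, batchSize = 32L,
                      lr = 1e-3, momentum = 0.9, flipAugment = TRUE,
                      seed = 1L, verbose = FALSE) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("training requires at least 2 classes present")
  if (nlevels(labels) != model$cfg@numClasses)
    stop("label levels (", nlevels(labels), ") must match configured classes (",
         model$cfg@numClasses, ")")
  model$classes <- levels(labels)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  if (epochs == 0L) return(list(model = model, log = log))
  size <- model$cfg@inputSize
  x_all <- .images_to_array(images, size)
  y <- as.integer(labels)
  n <- length(y)
  K <- model$cfg@numClasses
  vel <- rapply(model$params, function(z) z * 0, how = "replace")
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1, n, by = batchSize)) {
      bidx <- ord[start:min(start + batchSize - 1, n)]
      xb <- x_all[, , , bidx, drop = FALSE]
      if (flipAugment) {
        for (i in seq_along(bidx)) {
          if (stats::runif(1) < 0.5) xb[, , 1, i] <- xb[size:1, , 1, i]
          if (stats::runif(1) < 0.5) xb[, , 1, i] <- xb[, size:1, 1, i]
        }
      }
      onehot <- matrix(0, K, length(bidx))
      onehot[cbind(y[bidx], seq_along(bidx))] <- 1
      fw <- .dcnn_forward(model, xb, training = TRUE)
      model <- fw$model
      eps <- 1e-12
      ep_loss <- ep_loss - sum(log(pmax(fw$probs[onehot > 0], eps)))
      ep_correct <- ep_correct +
        sum(apply(fw$probs, 2, which.max) == y[bidx])
      grads <- .dcnn_backward(model, fw, onehot)
      for (nm in names(grads)) {
        for (pn in names(grads[[nm]])) {
          vel[[nm]][[pn]] <- momentum * vel[[nm]][[pn]] -
            lr * grads[[nm]][[pn]]
          model$params[[nm]][[pn]] <- model$params[[nm]][[pn]] +
            vel[[nm]][[pn]]
        }
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 accuracy = ep_correct / n))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, accuracy %.3f", ep,
                      ep_loss / n, ep_correct / n))
  }
  model$trained <- TRUE
  list(model = model, log = log)
}

#' Predict classes and confidences
#'
#' @param model a trained model from [trainDcnn].
#' @param images list of [RepresentativeImage-class] (or matrices).
#' @param batchSize inference batch size.
#' @return `list(labels, probabilities, confidence)`: predicted labels
#'   (argmax), an N x K matrix of class probabilities (rows sum to 1) and
#'   the max probability as percent.
#' @export
predictDcnn <- function(model, images, batchSize = 32L) {
  size <- model$cfg@inputSize
  x_all <- .images_to_array(images, size)
  n <- length(images)
  K <- model$cfg@numClasses
  probs <- matrix(0, n, K)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    fw <- .dcnn_forward(model, x_all[, , , idx, drop = FALSE],
                        training = FALSE)
    probs[idx, ] <- t(fw$probs)
  }
  classes <- if (!is.null(model$classes)) model$classes
             else as.character(seq_len(K))
  colnames(probs) <- classes
  lab <- factor(classes[max.col(probs, ties.method = "first")],
                levels = classes)
  list(labels = lab, probabilities = probs,
       confidence = 100 * apply(probs, 1, max))
}
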
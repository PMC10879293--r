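# Encoder and projection-head construction, forward/backward passes, and
# the frozen-encoder embedding contract used in phase 2.

#' Create a small convolutional encoder
#'
#' Initializes a four-block conv/batch-norm/ReLU network (He-initialized
#' kernels, unit batch-norm scale) whose output feature vector is
#' unit-normalized. The input side length must be divisible by 8 (three 2x2
#' mean-pooling stages precede the global pooling).
#'
#' @param inputSize square input side length in pixels.
#' @param channels output channels of the four conv blocks.
#' @param seed RNG seed for weight initialization.
#' @return a [ConvEncoder-class] object (trainable, not frozen).
#' @examples
#' enc <- convEncoder(32, seed = 1)
#' enc
#' @export
convEncoder <- function(inputSize = 32L, channels = c(16L, 32L, 64L, 64L),
                        seed = 1L) {
  inputSize <- as.integer(inputSize)
  channels <- as.integer(channels)
  if (length(channels) != 4L)
    stop("the encoder has exactly four convolutional blocks")
  if (inputSize %% 8L != 0L)
    stop("inputSize must be divisible by 8")
  set.seed(as.integer(seed))
  inCh <- c(3L, channels[-4L])
  weights <- list()
  bnStats <- list()
  for (l in 1:4) {
    weights[[paste0("K", l)]] <- heInitMatrix(9L * inCh[l], channels[l])
    weights[[paste0("g", l)]] <- rep(1, channels[l])   # batch-norm scale
    weights[[paste0("b", l)]] <- numeric(channels[l])  # batch-norm shift
    bnStats[[paste0("mean", l)]] <- numeric(channels[l])
    bnStats[[paste0("var", l)]] <- rep(1, channels[l])
  }
  new("ConvEncoder", weights = weights, bnStats = bnStats,
      channels = channels, inputSize = inputSize,
      featureDim = channels[4L], frozen = FALSE)
}

#' Freeze an encoder for phase-2 use
#'
#' @param encoder a [ConvEncoder-class].
#' @return the encoder with updates disallowed; [embedImages()] requires
#'   a frozen encoder.
#' @export
freezeEncoder <- function(encoder) {
  encoder@frozen <- TRUE
  encoder
}

#' @describeIn freezeEncoder whether the encoder is frozen
#' @export
isFrozen <- function(encoder) encoder@frozen

# Forward pass over an (H, W, 3, B) batch. In training mode batch norm
# uses batch statistics and the updated running statistics are returned;
# in evaluation mode (the default, and the only mode valid for a frozen
# encoder) the stored running statistics are used, making the pass
# deterministic. Returns the unit-normalized (B, d_h) feature matrix and,
# when keepCache, everything backward needs.
#' @keywords internal
encoderForward <- function(encoder, X, keepCache = FALSE, train = FALSE,
                           bnMomentum = 0.1) {
  w <- encoder@weights
  st <- encoder@bnStats
  cache <- if (keepCache) vector("list", 4L) else NULL
  for (l in 1:4) {
    g <- w[[paste0("g", l)]]; be <- w[[paste0("b", l)]]
    cv <- conv3x3Forward(X, w[[paste0("K", l)]], numeric(length(g)))
    if (train) {
      bn <- batchNormForward(cv$out, g, be)
      mkey <- paste0("mean", l); vkey <- paste0("var", l)
      st[[mkey]] <- (1 - bnMomentum) * st[[mkey]] + bnMomentum * bn$batchMean
      st[[vkey]] <- (1 - bnMomentum) * st[[vkey]] + bnMomentum * bn$batchVar
      bnOut <- bn$out
      bnCache <- bn$cache
    } else {
      bnOut <- batchNormEval(cv$out, g, be, st[[paste0("mean", l)]],
                             st[[paste0("var", l)]])
      bnCache <- NULL
    }
    rl <- reluForward(bnOut)
    pl <- if (l < 4L) meanPool2Forward(rl$out)
          else globalMeanPoolForward(rl$out)
    if (keepCache)
      cache[[l]] <- list(conv = cv$cache, bn = bnCache, relu = rl$cache,
                         pool = pl$cache)
    X <- pl$out
  }
  nn <- rowNormalizeForward(X)
  list(h = nn$out, cache = list(layers = cache, norm = nn$cache),
       bnStats = st)
}

# Backward pass through a training-mode forward. dH is the gradient with
# respect to the normalized features; returns gradients named like the
# weights.
#' @keywords internal
encoderBackward <- function(encoder, dH, cache) {
  w <- encoder@weights
  grads <- list()
  d <- rowNormalizeBackward(dH, cache$norm)
  for (l in 4:1) {
    lc <- cache$layers[[l]]
    d <- if (l == 4L) globalMeanPoolBackward(d, lc$pool)
         else meanPool2Backward(d, lc$pool)
    d <- reluBackward(d, lc$relu)
    bn <- batchNormBackward(d, w[[paste0("g", l)]], lc$bn)
    grads[[paste0("g", l)]] <- bn$dgamma
    grads[[paste0("b", l)]] <- bn$dbeta
    bk <- conv3x3Backward(bn$dX, w[[paste0("K", l)]], lc$conv)
    grads[[paste0("K", l)]] <- bk$dK
    d <- bk$dX
  }
  grads
}

#' Create a projection head
#'
#' One hidden ReLU layer of width \code{hiddenDim} followed by a linear map
#' to \code{outDim} and unit normalization. Used in phase 1 only.
#'
#' @param inDim encoder feature dimension d_h.
#' @param hiddenDim hidden width (default d_h).
#' @param outDim contrastive embedding dimension d_z.
#' @param seed RNG seed.
#' @return a [ProjectionHead-class].
#' @export
projectionHead <- function(inDim, hiddenDim = inDim, outDim = 128L,
                           seed = 1L) {
  set.seed(as.integer(seed))
  new("ProjectionHead",
      weights = list(W1 = heInitMatrix(inDim, hiddenDim),
                     b1 = numeric(hiddenDim),
                     W2 = heInitMatrix(hiddenDim, outDim),
                     # small nonzero bias: a fully dead hidden row still
                     # maps to a well-defined unit vector
                     b2 = rep(0.01, outDim)),
      inDim = as.integer(inDim), hiddenDim = as.integer(hiddenDim),
      outDim = as.integer(outDim))
}

#' Project encoder features into the contrastive embedding space
#'
#' @param head a [ProjectionHead-class].
#' @param h numeric matrix of features, one row per sample, \code{inDim}
#'   columns.
#' @return unit-norm embedding matrix with \code{outDim} columns.
#' @export
projectFeatures <- function(head, h) {
  if (!is.matrix(h)) h <- matrix(h, nrow = 1L)
  if (ncol(h) != head@inDim)
    stop(sprintf("feature dimension %d does not match head input %d",
                 ncol(h), head@inDim))
  projectionForward(head, h)$z
}

#' @keywords internal
projectionForward <- function(head, h) {
  w <- head@weights
  l1 <- linearForward(h, w$W1, w$b1)
  r1 <- reluForward(l1$out)
  l2 <- linearForward(r1$out, w$W2, w$b2)
  nn <- rowNormalizeForward(l2$out)
  list(z = nn$out,
       cache = list(l1 = l1$cache, r1 = r1$cache, l2 = l2$cache,
                    norm = nn$cache))
}

#' @keywords internal
projectionBackward <- function(head, dZ, cache) {
  w <- head@weights
  d <- rowNormalizeBackward(dZ, cache$norm)
  b2 <- linearBackward(d, w$W2, cache$l2)
  d <- reluBackward(b2$dX, cache$r1)
  b1 <- linearBackward(d, w$W1, cache$l1)
  list(grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db),
       dH = b1$dX)
}

#' Stack a list of equally sized images into an (H, W, 3, B) array
#'
#' @param images list of \code{h x w x 3} arrays.
#' @return a 4-d array with samples along the last dimension.
#' @export
stackImages <- function(images) {
  d <- dim(images[[1]])
  X <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) X[, , , i] <- images[[i]]
  X
}

#' Embed images with a frozen encoder
#'
#' Phase-2 feature extraction: deterministic, unit-norm features with no
#' parameter updates. Images are deterministically resized to the encoder's
#' input size when needed.
#'
#' @param encoder a frozen [ConvEncoder-class].
#' @param images an [ImageSet-class], a list of image arrays, or a single
#'   \code{h x w x 3} array.
#' @param batchSize internal forward-pass chunk size.
#' @return numeric matrix with one unit-norm feature row per image.
#' @export
embedImages <- function(encoder, images, batchSize = 256L) {
  if (!encoder@frozen)
    stop("phase-2 contract: the encoder must be frozen before embedding")
  if (is(images, "ImageSet")) images <- images@images
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  sz <- encoder@inputSize
  images <- lapply(images, function(im) {
    if (!all(dim(im)[1:2] == sz)) resizeImage(im, sz) else im
  })
  n <- length(images)
  out <- matrix(0, n, encoder@featureDim)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    out[idx, ] <- encoderForward(encoder, stackImages(images[idx]))$h
  }
  out
}
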
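#' @import methods
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# ImageSet
# ---------------------------------------------------------------------------

#' In-memory collection of labeled RGB images
#'
#' An \code{ImageSet} holds a list of \code{height x width x 3} numeric
#' arrays with pixel values in \code{[0, 1]}, a 0-based integer class label
#' per image, the class names, and an opaque source identifier per image
#' (a file path for directory-backed sets, a synthetic id otherwise).
#'
#' @slot images list of 3-channel numeric arrays, values in \code{[0, 1]}.
#' @slot labels integer vector, one 0-based class id per image.
#' @slot classNames character vector; \code{labels} index into it (0-based).
#' @slot sourceIds character vector, one id per image.
#'
#' @seealso [imageSet()], [readImageDirectory()], [generateSyntheticDataset()]
#' @export
setClass("ImageSet",
  representation(
    images     = "list",
    labels     = "integer",
    classNames = "character",
    sourceIds  = "character"
  )
)

setValidity("ImageSet", function(object) {
  n <- length(object@images)
  if (length(object@labels) != n)
    return("labels must have one entry per image")
  if (length(object@sourceIds) != n)
    return("sourceIds must have one entry per image")
  if (n > 0L) {
    if (any(object@labels < 0L))
      return("labels must be non-negative 0-based class ids")
    if (max(object@labels) >= length(object@classNames))
      return("labels reference classes beyond classNames")
    for (i in seq_len(min(n, 32L))) {
      d <- dim(object@images[[i]])
      if (length(d) != 3L || d[3] != 3L)
        return(sprintf("image %d is not a height x width x 3 array", i))
      v <- object@images[[i]]
      if (any(!is.finite(v)) || min(v) < 0 || max(v) > 1)
        return(sprintf("image %d has pixels outside [0, 1]", i))
    }
  }
  TRUE
})

#' Construct an ImageSet
#'
#' @param images list of \code{h x w x 3} arrays with values in \code{[0,1]}.
#' @param labels integer vector of 0-based class ids.
#' @param classNames character vector of class names; defaults to
#'   \code{"class_0" ...} covering the labels present.
#' @param sourceIds optional character ids; defaults to \code{"img_<i>"}.
#' @return an [ImageSet-class] object.
#' @export
imageSet <- function(images, labels,
                     classNames = NULL, sourceIds = NULL) {
  labels <- as.integer(labels)
  if (is.null(classNames)) {
    k <- if (length(labels)) max(labels) + 1L else 0L
    classNames <- sprintf("class_%d", seq_len(k) - 1L)
  }
  if (is.null(sourceIds))
    sourceIds <- sprintf("img_%d", seq_along(images))
  new("ImageSet", images = images, labels = labels,
      classNames = classNames, sourceIds = as.character(sourceIds))
}

#' @describeIn imageSet number of images
#' @param x,object an \code{ImageSet}.
#' @export
setMethod("length", "ImageSet", function(x) length(x@images))

#' Accessors for ImageSet
#'
#' \code{imageList()} returns the list of pixel arrays;
#' \code{imageLabels()} the 0-based integer labels; \code{classNames()}
#' the class names; \code{nClasses()} the number of classes.
#'
#' @param x an [ImageSet-class].
#' @return see individual descriptions.
#' @export
setGeneric("imageList", function(x) standardGeneric("imageList"))

#' @rdname imageList
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname imageList
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname imageList
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname imageList
#' @export
setMethod("imageList", "ImageSet", function(x) x@images)

#' @rdname imageList
#' @export
setMethod("imageLabels", "ImageSet", function(x) x@labels)

#' @rdname imageList
#' @export
setMethod("classNames", "ImageSet", function(x) x@classNames)

#' @rdname imageList
#' @export
setMethod("nClasses", "ImageSet", function(x) length(x@classNames))

#' @rdname imageList
#' @param i integer or logical index of images to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ImageSet", function(x, i, j, ..., drop = FALSE) {
  new("ImageSet", images = x@images[i], labels = x@labels[i],
      classNames = x@classNames, sourceIds = x@sourceIds[i])
})

setMethod("show", "ImageSet", function(object) {
  n <- length(object@images)
  sz <- if (n) paste(dim(object@images[[1]])[1:2], collapse = "x") else "?"
  cat(sprintf("ImageSet: %d images (%s px), %d classes\n",
              n, sz, length(object@classNames)))
  if (n) {
    tab <- table(factor(object@labels, levels = seq_along(object@classNames) - 1L))
    cat("  per-class counts:", paste(as.integer(tab), collapse = " "), "\n")
  }
})

# ---------------------------------------------------------------------------
# AugmentationSpec
# ---------------------------------------------------------------------------

#' Stochastic two-view augmentation specification
#'
#' Configures the four augmentation operators applied, in the fixed order
#' A -> B -> C -> D, when contrastive training views are generated:
#' \describe{
#'   \item{A}{random aspect-ratio crop with area fraction drawn uniformly
#'     from \code{cropAreaRange}, then resize to \code{outputSize};}
#'   \item{B}{horizontal flip with probability \code{flipProb};}
#'   \item{C}{brightness/contrast/saturation jitter of strength
#'     \code{colorJitterStrength}, applied with probability
#'     \code{colorDistortProb};}
#'   \item{D}{conversion to 3-channel grayscale with probability
#'     \code{grayscaleProb}.}
#' }
#' When A is disabled the image is deterministically resized to
#' \code{outputSize} first.
#'
#' @slot ops character vector, subset of \code{c("A","B","C","D")}.
#' @slot cropAreaRange numeric(2), crop area fraction bounds in (0, 1].
#' @slot flipProb numeric, horizontal-flip probability.
#' @slot colorDistortProb numeric, probability the color jitter fires.
#' @slot grayscaleProb numeric, probability of grayscale conversion.
#' @slot colorJitterStrength numeric, max relative perturbation of
#'   brightness/contrast/saturation.
#' @slot outputSize integer, side length of the square output view.
#' @export
setClass("AugmentationSpec",
  representation(
    ops                 = "character",
    cropAreaRange       = "numeric",
    flipProb            = "numeric",
    colorDistortProb    = "numeric",
    grayscaleProb       = "numeric",
    colorJitterStrength = "numeric",
    outputSize          = "integer"
  )
)

setValidity("AugmentationSpec", function(object) {
  if (length(object@ops) && !all(object@ops %in% c("A", "B", "C", "D")))
    return("ops must be a subset of A, B, C, D")
  r <- object@cropAreaRange
  if (length(r) != 2L || r[1] <= 0 || r[2] > 1 || r[1] > r[2])
    return("cropAreaRange must be within (0, 1] with low <= high")
  for (p in c(object@flipProb, object@colorDistortProb, object@grayscaleProb))
    if (!is.finite(p) || p < 0 || p > 1)
      return("probabilities must lie in [0, 1]")
  if (object@outputSize < 1L)
    return("outputSize must be a positive integer")
  if (object@colorJitterStrength < 0)
    return("colorJitterStrength must be non-negative")
  TRUE
})

#' Construct an AugmentationSpec
#'
#' @param ops operators to enable, either a character vector such as
#'   \code{c("A","B","C")} or a compact string such as \code{"ABC"}.
#' @param cropAreaRange crop area fraction bounds (operator A).
#' @param flipProb horizontal flip probability (operator B).
#' @param colorDistortProb probability the color jitter fires (operator C).
#' @param grayscaleProb grayscale conversion probability (operator D).
#' @param colorJitterStrength relative brightness/contrast/saturation
#'   jitter magnitude.
#' @param outputSize side length in pixels of the output view.
#' @return an [AugmentationSpec-class] object.
#' @examples
#' augmentationSpec("ABC", outputSize = 32)
#' @export
augmentationSpec <- function(ops = "ABC",
                             cropAreaRange = c(0.2, 1.0),
                             flipProb = 0.5,
                             colorDistortProb = 0.8,
                             grayscaleProb = 0.2,
                             colorJitterStrength = 0.4,
                             outputSize = 224L) {
  if (length(ops) == 1L && nchar(ops) != 1L)
    ops <- strsplit(ops, "")[[1]]
  new("AugmentationSpec", ops = unique(toupper(ops)),
      cropAreaRange = as.numeric(cropAreaRange),
      flipProb = flipProb, colorDistortProb = colorDistortProb,
      grayscaleProb = grayscaleProb,
      colorJitterStrength = colorJitterStrength,
      outputSize = as.integer(outputSize))
}

setMethod("show", "AugmentationSpec", function(object) {
  cat(sprintf(
    "AugmentationSpec: ops=%s crop=[%.2f,%.2f] flip=%.2f color=%.2f(j=%.2f) gray=%.2f out=%dpx\n",
    paste(object@ops, collapse = ""), object@cropAreaRange[1],
    object@cropAreaRange[2], object@flipProb, object@colorDistortProb,
    object@colorJitterStrength, object@grayscaleProb, object@outputSize))
})

# ---------------------------------------------------------------------------
# TrainConfig
# ---------------------------------------------------------------------------

#' Phase-1 pre-training configuration
#'
#' Hyperparameters of the supervised contrastive pre-training loop:
#' SGD with momentum and weight decay, a linear warmup followed by cosine
#' annealing restarted over three equal segments whose peak learning rates
#' decay geometrically by \code{lrDecay} (a plain step schedule is
#' available via \code{schedule = "step"}).
#'
#' Defaults mirror the best full-scale configuration (batch size 192,
#' temperature 0.1, 500 epochs, initial learning rate 0.05, decay 0.1,
#' momentum 0.9, weight decay 5e-4); desk-scale runs override them.
#'
#' @slot batchSize integer, number N of original images per minibatch
#'   (each contributes two views).
#' @slot tau numeric, contrastive temperature (> 0).
#' @slot epochs integer, training epochs.
#' @slot baseLR,lrDecay,momentum,weightDecay numeric optimizer settings.
#' @slot warmupEpochs integer, epochs of linear learning-rate ramp.
#' @slot schedule character, \code{"cosine"} or \code{"step"}.
#' @slot seed integer, RNG seed making the run reproducible.
#' @slot augment an [AugmentationSpec-class].
#' @export
setClass("TrainConfig",
  representation(
    batchSize    = "integer",
    tau          = "numeric",
    epochs       = "integer",
    baseLR       = "numeric",
    lrDecay      = "numeric",
    momentum     = "numeric",
    weightDecay  = "numeric",
    warmupEpochs = "integer",
    schedule     = "character",
    seed         = "integer",
    augment      = "AugmentationSpec"
  )
)

setValidity("TrainConfig", function(object) {
  if (object@tau <= 0) return("temperature tau must be > 0")
  if (object@batchSize < 1L) return("batchSize must be positive")
  if (object@epochs < 1L) return("epochs must be positive")
  if (object@warmupEpochs < 0L) return("warmupEpochs must be >= 0")
  if (!object@schedule %in% c("cosine", "step"))
    return("schedule must be 'cosine' or 'step'")
  if (length(object@augment@ops) == 0L)
    return("no augmentation configured: training requires at least one operator")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param batchSize minibatch size N (original images; the loss sees 2N views).
#' @param tau contrastive temperature.
#' @param epochs number of passes over the dataset.
#' @param baseLR initial learning rate.
#' @param lrDecay decay factor applied at each of the three annealing
#'   segments (or step drops).
#' @param momentum SGD momentum.
#' @param weightDecay L2 weight decay.
#' @param warmupEpochs linear warmup length in epochs.
#' @param schedule \code{"cosine"} (three cosine segments with decaying
#'   peaks) or \code{"step"} (three multiplicative drops).
#' @param seed RNG seed.
#' @param augment an [AugmentationSpec-class].
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(batchSize = 192L, tau = 0.1, epochs = 500L,
                        baseLR = 0.05, lrDecay = 0.1, momentum = 0.9,
                        weightDecay = 5e-4, warmupEpochs = 10L,
                        schedule = "cosine", seed = 1L,
                        augment = augmentationSpec()) {
  new("TrainConfig", batchSize = as.integer(batchSize), tau = tau,
      epochs = as.integer(epochs), baseLR = baseLR, lrDecay = lrDecay,
      momentum = momentum, weightDecay = weightDecay,
      warmupEpochs = as.integer(warmupEpochs), schedule = schedule,
      seed = as.integer(seed), augment = augment)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: N=%d tau=%.3g epochs=%d lr=%.3g(decay %.2g, warmup %d, %s) mom=%.2g wd=%.1e seed=%d\n",
    object@batchSize, object@tau, object@epochs, object@baseLR,
    object@lrDecay, object@warmupEpochs, object@schedule,
    object@momentum, object@weightDecay, object@seed))
})

# ---------------------------------------------------------------------------
# Encoder / projection head
# ---------------------------------------------------------------------------

#' Small convolutional encoder
#'
#' A four-block convolutional network of conv(3x3, stride 1, padding 1) ->
#' batch norm -> ReLU -> 2x2 mean pooling (global mean pooling after the
#' last block), producing a feature vector that is unit-normalized at the
#' encoder output. Batch normalization uses batch statistics during
#' training and running statistics once frozen, so phase-2 embeddings are
#' deterministic. The classification head a conventional CNN would carry is
#' absent by construction: the encoder maps images to features only.
#'
#' @slot weights named list of kernels and batch-norm scale/shift vectors.
#' @slot bnStats named list of running mean/variance per block.
#' @slot channels integer vector of output channels per conv block.
#' @slot inputSize integer, expected square input side length.
#' @slot featureDim integer, dimension of the output feature vector h.
#' @slot frozen logical, whether parameters may still be updated.
#' @export
setClass("ConvEncoder",
  representation(
    weights    = "list",
    bnStats    = "list",
    channels   = "integer",
    inputSize  = "integer",
    featureDim = "integer",
    frozen     = "logical"
  )
)

setMethod("show", "ConvEncoder", function(object) {
  cat(sprintf("ConvEncoder: %dx%d input, channels %s, d_h=%d, %s\n",
              object@inputSize, object@inputSize,
              paste(object@channels, collapse = "-"),
              object@featureDim,
              if (object@frozen) "frozen" else "trainable"))
})

#' Projection head mapping encoder features into the contrastive space
#'
#' A one-hidden-layer MLP (ReLU) from the encoder feature dimension to the
#' contrastive embedding dimension, followed by unit normalization. It is
#' used only during phase-1 pre-training and discarded afterwards.
#'
#' @slot weights named list with \code{W1}, \code{b1}, \code{W2}, \code{b2}.
#' @slot inDim,hiddenDim,outDim integer dimensions.
#' @export
setClass("ProjectionHead",
  representation(
    weights   = "list",
    inDim     = "integer",
    hiddenDim = "integer",
    outDim    = "integer"
  )
)

setMethod("show", "ProjectionHead", function(object) {
  cat(sprintf("ProjectionHead: %d -> %d -> %d (unit-normalized)\n",
              object@inDim, object@hiddenDim, object@outDim))
})

# ---------------------------------------------------------------------------
# Few-shot episode containers
# ---------------------------------------------------------------------------

#' One N-way K-shot episode
#'
#' Support and query images with episode-local labels \code{0..nWay-1};
#' \code{classMap[m + 1]} gives the dataset class id behind episode-local
#' class \code{m}.
#'
#' @slot support,query [ImageSet-class] objects in the episode-local label
#'   space.
#' @slot classMap integer vector mapping episode-local ids to dataset ids.
#' @slot nWay,kShot,qQuery integer episode geometry.
#' @export
setClass("Episode",
  representation(
    support  = "ImageSet",
    query    = "ImageSet",
    classMap = "integer",
    nWay     = "integer",
    kShot    = "integer",
    qQuery   = "integer"
  )
)

setValidity("Episode", function(object) {
  if (length(object@support) != object@nWay * object@kShot)
    return("support size must equal nWay * kShot")
  if (length(object@query) != object@nWay * object@qQuery)
    return("query size must equal nWay * qQuery")
  for (m in seq_len(object@nWay) - 1L) {
    if (sum(object@support@labels == m) != object@kShot)
      return(sprintf("episode class %d lacks exactly kShot support items", m))
    if (sum(object@query@labels == m) != object@qQuery)
      return(sprintf("episode class %d lacks exactly qQuery query items", m))
  }
  if (length(intersect(object@support@sourceIds, object@query@sourceIds)))
    return("support and query sets overlap")
  TRUE
})

setMethod("show", "Episode", function(object) {
  cat(sprintf("Episode: %d-way %d-shot, %d queries/class (dataset classes: %s)\n",
              object@nWay, object@kShot, object@qQuery,
              paste(object@classMap, collapse = ",")))
})

#' Class prototypes of one episode
#'
#' @slot prototypes numeric matrix, one row per episode-local class
#'   (the per-class mean feature vector).
#' @slot classMap integer vector mapping episode-local ids to dataset ids.
#' @export
setClass("PrototypeSet",
  representation(prototypes = "matrix", classMap = "integer")
)

setValidity("PrototypeSet", function(object) {
  if (!all(is.finite(object@prototypes)))
    return("prototypes must be finite")
  if (nrow(object@prototypes) != length(object@classMap))
    return("one classMap entry per prototype required")
  TRUE
})

#' Episodic evaluation result
#'
#' Per-episode top-1 accuracies, their mean, the Bessel (n-1 denominator)
#' standard deviation, the 95% confidence half-width 1.96 s / sqrt(n), and
#' the cumulative confusion matrix over all query predictions in the
#' episode-local label space.
#'
#' @slot perEpisodeAcc numeric vector of per-episode accuracies in [0, 1].
#' @slot meanAcc,besselSD,halfWidth numeric summary statistics.
#' @slot nEpisodes integer, number of episodes.
#' @slot confusion integer matrix, rows = true class, cols = predicted.
#' @slot nWay,kShot,qQuery integer episode geometry.
#' @export
setClass("EvalResult",
  representation(
    perEpisodeAcc = "numeric",
    meanAcc       = "numeric",
    besselSD      = "numeric",
    halfWidth     = "numeric",
    nEpisodes     = "integer",
    confusion     = "matrix",
    nWay          = "integer",
    kShot         = "integer",
    qQuery        = "integer"
  )
)

setValidity("EvalResult", function(object) {
  if (length(object@perEpisodeAcc) != object@nEpisodes)
    return("one accuracy per episode required")
  if (abs(object@meanAcc - mean(object@perEpisodeAcc)) > 1e-12)
    return("meanAcc must equal the mean of perEpisodeAcc")
  if (any(rowSums(object@confusion) != object@nEpisodes * object@qQuery))
    return("confusion row sums must equal nEpisodes * qQuery")
  TRUE
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: %d-way %d-shot over %d episodes\n  accuracy %s%%\n",
              object@nWay, object@kShot, object@nEpisodes,
              formatAccuracy(object)))
})

# ---------------------------------------------------------------------------
# Synthetic data configuration
# ---------------------------------------------------------------------------

#' Per-class recipe for synthetic leaf images
#'
#' @slot lesionHue numeric, lesion hue angle in degrees [0, 360).
#' @slot lesionCountRange integer(2), min/max lesion spots per image.
#' @slot lesionRadiusRange numeric(2), lesion radii as fractions of the
#'   image side.
#' @slot backgroundHue numeric, leaf-blade hue angle in degrees.
#' @slot noiseSD numeric, per-pixel Gaussian noise standard deviation.
#' @export
setClass("SyntheticClassSpec",
  representation(
    lesionHue         = "numeric",
    lesionCountRange  = "integer",
    lesionRadiusRange = "numeric",
    backgroundHue     = "numeric",
    noiseSD           = "numeric"
  )
)

setValidity("SyntheticClassSpec", function(object) {
  if (object@lesionHue < 0 || object@lesionHue >= 360 ||
      object@backgroundHue < 0 || object@backgroundHue >= 360)
    return("hues must lie in [0, 360)")
  if (object@lesionCountRange[1] > object@lesionCountRange[2] ||
      object@lesionRadiusRange[1] > object@lesionRadiusRange[2])
    return("ranges must satisfy low <= high")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' @rdname SyntheticClassSpec-class
#' @param lesionHue,lesionCountRange,lesionRadiusRange,backgroundHue,noiseSD
#'   see slot descriptions.
#' @export
syntheticClassSpec <- function(lesionHue, lesionCountRange = c(4L, 8L),
                               lesionRadiusRange = c(0.05, 0.12),
                               backgroundHue = (lesionHue + 120) %% 360,
                               noiseSD = 0.05) {
  new("SyntheticClassSpec", lesionHue = lesionHue,
      lesionCountRange = as.integer(lesionCountRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      backgroundHue = backgroundHue, noiseSD = noiseSD)
}

#' Synthetic dataset configuration
#'
#' Defaults give the desk-scale profile: 10 classes x 100 images of
#' 32 x 32 pixels, with class lesion hues spaced uniformly around the color
#' wheel so that color is the dominant class signal.
#'
#' @slot nClasses,perClass,imageSize,seed integers.
#' @slot classSpecs list of [SyntheticClassSpec-class], one per class
#'   (auto-derived when empty).
#' @export
setClass("SyntheticDatasetConfig",
  representation(
    nClasses   = "integer",
    perClass   = "integer",
    imageSize  = "integer",
    seed       = "integer",
    classSpecs = "list"
  )
)

setValidity("SyntheticDatasetConfig", function(object) {
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@perClass < 1L) return("perClass must be >= 1")
  if (object@imageSize < 16L) return("imageSize must be >= 16")
  if (length(object@classSpecs) &&
      length(object@classSpecs) != object@nClasses)
    return("classSpecs must have one entry per class when given")
  TRUE
})

#' @rdname SyntheticDatasetConfig-class
#' @param nClasses,perClass,imageSize,seed see slot descriptions.
#' @param classSpecs optional explicit list of per-class recipes.
#' @export
syntheticDatasetConfig <- function(nClasses = 10L, perClass = 100L,
                                   imageSize = 32L, seed = 1L,
                                   classSpecs = list()) {
  new("SyntheticDatasetConfig", nClasses = as.integer(nClasses),
      perClass = as.integer(perClass), imageSize = as.integer(imageSize),
      seed = as.integer(seed), classSpecs = classSpecs)
}

setMethod("show", "SyntheticDatasetConfig", function(object) {
  cat(sprintf("SyntheticDatasetConfig: %d classes x %d images, %dpx, seed %d\n",
              object@nClasses, object@perClass, object@imageSize,
              object@seed))
})
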
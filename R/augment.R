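# The two-view augmentation pipeline: operators A (random resized crop),
# B (horizontal flip), C (color distortion), D (random grayscale), applied
# in that fixed order, and contrastive batch assembly with interleaved
# views. All randomness comes from R's global RNG, so set.seed() upstream
# makes every pipeline call reproducible.

#' Deterministically resize an image to a square
#'
#' Bilinear resize (via EBImage) of an \code{h x w x 3} array to
#' \code{size x size x 3}, with output clamped to [0, 1].
#'
#' @param img image array with values in [0, 1].
#' @param size output side length in pixels.
#' @return resized image array.
#' @export
resizeImage <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img, colormode = "Color"), w = size, h = size))
  dim(out) <- c(size, size, 3L)
  pmin(pmax(out, 0), 1)
}

#' Sample a random aspect-ratio crop window (operator A)
#'
#' Draws an area fraction uniformly from \code{areaRange} and an aspect
#' ratio log-uniformly from \code{aspectRange}, retrying up to ten times
#' until the window fits; the fallback is a centered square crop whose area
#' fraction still lies inside \code{areaRange}.
#'
#' @param h,w input image dimensions in pixels.
#' @param areaRange numeric(2) crop area fraction bounds.
#' @param aspectRange numeric(2) width/height aspect-ratio bounds.
#' @return list with integer fields \code{y, x, ch, cw} (top-left corner
#'   and window size) and \code{areaFrac}, the realized area fraction.
#' @export
sampleCropWindow <- function(h, w, areaRange = c(0.2, 1.0),
                             aspectRange = c(3 / 4, 4 / 3)) {
  area <- h * w
  for (attempt in 1:10) {
    targetArea <- runif(1, areaRange[1], areaRange[2]) * area
    ratio <- exp(runif(1, log(aspectRange[1]), log(aspectRange[2])))
    # ceiling keeps the realized pixel area >= the drawn target area, so
    # the empirical area fraction never drops below areaRange[1]
    cw <- as.integer(ceiling(sqrt(targetArea * ratio)))
    ch <- as.integer(ceiling(sqrt(targetArea / ratio)))
    if (cw >= 1L && ch >= 1L && cw <= w && ch <= h) {
      x <- if (w == cw) 1L else sample.int(w - cw + 1L, 1L)
      y <- if (h == ch) 1L else sample.int(h - ch + 1L, 1L)
      return(list(y = y, x = x, ch = ch, cw = cw,
                  areaFrac = (ch * cw) / area))
    }
  }
  side <- min(h, w, as.integer(floor(sqrt(areaRange[2] * area))))
  list(y = (h - side) %/% 2L + 1L, x = (w - side) %/% 2L + 1L,
       ch = side, cw = side, areaFrac = (side * side) / area)
}

#' @keywords internal
applyGrayscale <- function(img) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  array(rep(lum, 3L), dim = dim(img))
}

# Brightness, contrast, saturation jitter with factors drawn uniformly in
# [max(0, 1 - s), 1 + s], applied in that fixed order.
#' @keywords internal
applyColorJitter <- function(img, strength) {
  f <- runif(3, max(0, 1 - strength), 1 + strength)
  img <- img * f[1]
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  img <- (img - mean(lum)) * f[2] + mean(lum)
  gray <- array(rep(lum, 3L), dim = dim(img))
  img <- gray + f[3] * (img - gray)
  pmin(pmax(img, 0), 1)
}

#' Build the stochastic augmentation transform
#'
#' Returns a function that maps one image array to one augmented view of
#' size \code{outputSize}, applying the enabled operators in the fixed
#' order A, B, C, D. When A is disabled the image is deterministically
#' resized first so every view has the configured output size.
#'
#' @param spec an [AugmentationSpec-class]; \code{ops} must be non-empty.
#' @return function taking an \code{h x w x 3} array and returning an
#'   \code{outputSize x outputSize x 3} array in [0, 1].
#' @examples
#' set.seed(1)
#' tf <- makeAugmentationPipeline(augmentationSpec("AB", outputSize = 16))
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' dim(tf(img))
#' @export
makeAugmentationPipeline <- function(spec) {
  validObject(spec)
  if (length(spec@ops) == 0L)
    stop("no augmentation configured: spec$ops is empty")
  ops <- spec@ops
  size <- spec@outputSize
  function(img) {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    if ("A" %in% ops) {
      d <- dim(img)
      win <- sampleCropWindow(d[1], d[2], spec@cropAreaRange)
      img <- img[win$y:(win$y + win$ch - 1L),
                 win$x:(win$x + win$cw - 1L), , drop = FALSE]
    }
    img <- resizeImage(img, size)
    if ("B" %in% ops && runif(1) < spec@flipProb)
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    if ("C" %in% ops && runif(1) < spec@colorDistortProb)
      img <- applyColorJitter(img, spec@colorJitterStrength)
    if ("D" %in% ops && runif(1) < spec@grayscaleProb)
      img <- applyGrayscale(img)
    img
  }
}

#' Assemble a two-view contrastive batch
#'
#' Applies the transform twice, independently, to each of the N input
#' images and interleaves the resulting 2N views so that views 2k-1 and 2k
#' (1-based) are the two augmentations of original image k, with the
#' label duplicated accordingly. This interleaved layout is the canonical
#' positive-pair bookkeeping the contrastive loss relies on.
#'
#' @param images list of image arrays, or an [ImageSet-class].
#' @param labels integer labels, one per image (taken from the
#'   \code{ImageSet} when omitted).
#' @param transform a function from [makeAugmentationPipeline()].
#' @return list with \code{views} (list of 2N arrays) and \code{labels}
#'   (integer vector of length 2N).
#' @export
buildTwoViewBatch <- function(images, transform, labels = NULL) {
  if (is(images, "ImageSet")) {
    if (is.null(labels)) labels <- images@labels
    images <- images@images
  }
  n <- length(images)
  if (n < 1L) stop("empty batch: at least one image is required")
  if (length(labels) != n) stop("one label per image is required")
  views <- vector("list", 2L * n)
  outLabels <- integer(2L * n)
  for (k in seq_len(n)) {
    views[[2L * k - 1L]] <- transform(images[[k]])
    views[[2L * k]]      <- transform(images[[k]])
    outLabels[c(2L * k - 1L, 2L * k)] <- labels[k]
  }
  list(views = views, labels = outLabels)
}
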
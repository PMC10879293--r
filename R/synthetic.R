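# Seeded generator of class-structured leaf-like images. Each class owns a
# lesion hue (evenly spaced on the color wheel) and a leaf-blade hue; the
# HSV value channel is solved per hue so that luminance is approximately
# constant across classes. Hue therefore carries (almost) all of the class
# signal, which is the property that makes the testbed color-dependent:
# grayscaling the images collapses class separability.

# Vectorized HSV (h in degrees, s, v in [0,1]) -> N x 3 RGB matrix.
#' @keywords internal
hsv2rgbMatrix <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  sel <- function(k) i == k
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  cbind(r, g, b)
}

# HSV value giving luminance ~ targetLum at the given hue/saturation, so
# that classes differ in hue but not (much) in brightness.
#' @keywords internal
isoLuminantValue <- function(hue, sat, targetLum = 0.5) {
  rgb1 <- hsv2rgbMatrix(hue, rep(sat, length(hue)), rep(1, length(hue)))
  lum1 <- rgb1 %*% c(0.299, 0.587, 0.114)
  pmin(1, targetLum / pmax(as.numeric(lum1), 1e-6))
}

#' @keywords internal
defaultClassSpecs <- function(nClasses) {
  hues <- (seq_len(nClasses) - 1L) * 360 / nClasses
  lapply(hues, function(h) syntheticClassSpec(lesionHue = h))
}

#' @keywords internal
renderLeafImage <- function(size, spec) {
  ax <- seq_len(size) - (size + 1) / 2
  gx <- matrix(ax, size, size)            # varies down rows
  gy <- t(gx)
  # elliptical leaf blade with jittered axes
  a <- size * runif(1, 0.38, 0.48)
  b <- size * runif(1, 0.30, 0.42)
  theta <- runif(1, -0.4, 0.4)
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  leaf <- (xr / a)^2 + (yr / b)^2 <= 1

  sat <- 0.65
  bgHue <- (spec@backgroundHue + runif(1, -8, 8)) %% 360
  vLeaf <- isoLuminantValue(bgHue, sat) * runif(1, 0.95, 1.05)
  leafRGB <- hsv2rgbMatrix(rep(bgHue, 1), sat, pmin(vLeaf, 1))
  # neutral matte backdrop behind the leaf, no class information
  img <- array(runif(1, 0.42, 0.52), c(size, size, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[leaf] <- leafRGB[ch]
    img[, , ch] <- plane
  }
  # smooth vertical illumination gradient, class-independent
  grad <- matrix(seq(-0.03, 0.03, length.out = size), size, size)
  img <- img + array(rep(grad, 3), c(size, size, 3))

  nLesions <- sample(seq(spec@lesionCountRange[1], spec@lesionCountRange[2]),
                     1L)
  lesHueBase <- spec@lesionHue
  inside <- which(leaf, arr.ind = TRUE)
  for (l in seq_len(nLesions)) {
    c0 <- inside[sample.int(nrow(inside), 1L), ]
    r <- size * runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
    if (2 * r >= size)
      stop("image_size too small for the configured lesion radii")
    hue <- (lesHueBase + runif(1, -8, 8)) %% 360
    satL <- runif(1, 0.55, 0.8)
    vL <- min(1, isoLuminantValue(hue, satL) * runif(1, 0.95, 1.05))
    rgb <- hsv2rgbMatrix(hue, satL, vL)
    mask <- (gx - ax[c0[1]])^2 + (gy - ax[c0[2]])^2 <= r^2
    mask <- mask & leaf
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- rgb[ch]
      img[, , ch] <- plane
    }
  }
  img <- img + array(rnorm(size * size * 3, sd = spec@noiseSD),
                     c(size, size, 3))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic class-structured leaf image dataset
#'
#' Deterministic given \code{config@seed}. Each image is an elliptical
#' leaf blade in the class background hue over a neutral backdrop, with a
#' class-dependent number of circular lesion spots in the class lesion hue
#' (per-image jitter in hue, position, size, and saturation) plus Gaussian
#' pixel noise. Class specs default to lesion hues evenly spaced around the
#' color wheel at near-constant luminance, so color is the dominant class
#' signal.
#'
#' @param config a [SyntheticDatasetConfig-class].
#' @return an [ImageSet-class] with labels \code{0..nClasses-1}.
#' @examples
#' ds <- generateSyntheticDataset(syntheticDatasetConfig(3, 4, 32, seed = 1))
#' ds
#' @export
generateSyntheticDataset <- function(config) {
  validObject(config)
  specs <- if (length(config@classSpecs)) config@classSpecs
           else defaultClassSpecs(config@nClasses)
  for (sp in specs) validObject(sp)
  if (min(vapply(specs, function(s) s@lesionRadiusRange[1], 0)) *
      config@imageSize < 0.5)
    warning("lesions smaller than one pixel at this image_size")
  set.seed(config@seed)
  n <- config@nClasses * config@perClass
  images <- vector("list", n)
  labels <- integer(n)
  ids <- character(n)
  i <- 0L
  for (cls in seq_len(config@nClasses) - 1L) {
    for (k in seq_len(config@perClass)) {
      i <- i + 1L
      images[[i]] <- renderLeafImage(config@imageSize, specs[[cls + 1L]])
      labels[i] <- cls
      ids[i] <- sprintf("synthetic_c%02d_%04d", cls, k)
    }
  }
  new("ImageSet", images = images, labels = labels,
      classNames = sprintf("synthetic_class_%02d",
                           seq_len(config@nClasses) - 1L),
      sourceIds = ids)
}

#' Class-disjoint base/novel split
#'
#' Randomly assigns \code{nNovelClasses} classes to a novel (target-domain)
#' set never seen during pre-training; the remaining classes form the base
#' (source-domain) set. Labels are re-indexed contiguously within each part.
#'
#' @param dataset an [ImageSet-class].
#' @param nNovelClasses number of held-out classes.
#' @param seed RNG seed.
#' @return list with \code{base} and \code{novel} [ImageSet-class] objects
#'   whose class sets are disjoint.
#' @export
holdoutSplit <- function(dataset, nNovelClasses, seed = 1L) {
  k <- length(dataset@classNames)
  if (k < nNovelClasses + 2L)
    stop("too few classes: need at least nNovelClasses + 2")
  set.seed(as.integer(seed))
  novelClasses <- sort(sample(seq_len(k) - 1L, nNovelClasses))
  baseClasses <- setdiff(seq_len(k) - 1L, novelClasses)
  subsetClasses <- function(keep) {
    sel <- dataset@labels %in% keep
    relabel <- match(dataset@labels[sel], keep) - 1L
    new("ImageSet", images = dataset@images[sel],
        labels = as.integer(relabel),
        classNames = dataset@classNames[keep + 1L],
        sourceIds = dataset@sourceIds[sel])
  }
  list(base = subsetClasses(baseClasses), novel = subsetClasses(novelClasses))
}

#' Mean-color nearest-centroid baseline accuracy
#'
#' A deliberately crude classifier: each image is reduced to its mean RGB
#' color (or mean luminance when \code{grayscale}), class centroids are the
#' per-class means, and every image is assigned to its nearest centroid.
#' Returns train-set accuracy. High accuracy confirms color separability of
#' a dataset; the drop under \code{grayscale = TRUE} quantifies how much of
#' the class signal lives in color alone.
#'
#' @param dataset an [ImageSet-class].
#' @param grayscale reduce images to luminance before averaging.
#' @return accuracy in [0, 1].
#' @export
meanColorBaseline <- function(dataset, grayscale = FALSE) {
  feats <- t(vapply(dataset@images, function(im) {
    if (grayscale) {
      l <- mean(0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3])
      c(l, l, l)
    } else {
      c(mean(im[, , 1]), mean(im[, , 2]), mean(im[, , 3]))
    }
  }, numeric(3)))
  nWay <- length(unique(dataset@labels))
  proto <- computePrototypes(feats, dataset@labels, nWay)
  cls <- classifyQueries(feats, proto)
  episodeAccuracy(cls$pred, dataset@labels)
}
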
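# Phase 2: episodic N-way K-shot sampling, nearest-centroid (prototype)
# classification under a squared-Euclidean softmax, and evaluation
# statistics (mean episodic top-1 accuracy, Bessel standard deviation,
# 1.96 s / sqrt(n) half-width, cumulative confusion matrix).

#' Sample one N-way K-shot episode
#'
#' Draws \code{nWay} classes uniformly without replacement, then
#' \code{kShot + qQuery} images per class without replacement, split into
#' disjoint support and query sets carrying episode-local labels
#' \code{0..nWay-1}. Uses R's global RNG; seed upstream for
#' reproducibility.
#'
#' @param dataset an [ImageSet-class].
#' @param nWay,kShot,qQuery episode geometry.
#' @return an [Episode-class].
#' @export
sampleEpisode <- function(dataset, nWay, kShot, qQuery = 15L) {
  idx <- episodeIndices(dataset@labels, nWay, kShot, qQuery,
                        classNames = dataset@classNames)
  mk <- function(ix, localLabels)
    new("ImageSet", images = dataset@images[ix],
        labels = as.integer(localLabels),
        classNames = sprintf("episode_%d", seq_len(nWay) - 1L),
        sourceIds = dataset@sourceIds[ix])
  new("Episode",
      support = mk(idx$support, idx$supportLabels),
      query = mk(idx$query, idx$queryLabels),
      classMap = idx$classMap,
      nWay = as.integer(nWay), kShot = as.integer(kShot),
      qQuery = as.integer(qQuery))
}

# Index-level episode sampler shared by sampleEpisode and evaluateFewShot
# (the latter samples in feature space after embedding the dataset once).
#' @keywords internal
episodeIndices <- function(labels, nWay, kShot, qQuery, classNames = NULL) {
  classes <- sort(unique(labels))
  if (length(classes) < nWay)
    stop(sprintf("dataset has %d classes but nWay=%d requested",
                 length(classes), nWay))
  need <- kShot + qQuery
  counts <- table(labels)
  short <- as.integer(names(counts))[counts < need]
  if (length(short)) {
    nm <- if (!is.null(classNames)) classNames[short[1] + 1L]
          else as.character(short[1])
    stop(sprintf(
      "class '%s' has %d images but kShot + qQuery = %d are required",
      nm, counts[as.character(short[1])], need))
  }
  classMap <- sort(sample(classes, nWay))
  support <- integer(0); query <- integer(0)
  supportLabels <- integer(0); queryLabels <- integer(0)
  for (m in seq_len(nWay)) {
    pool <- which(labels == classMap[m])
    pick <- sample(pool, need)
    support <- c(support, pick[seq_len(kShot)])
    query <- c(query, pick[kShot + seq_len(qQuery)])
    supportLabels <- c(supportLabels, rep(m - 1L, kShot))
    queryLabels <- c(queryLabels, rep(m - 1L, qQuery))
  }
  list(support = support, query = query, supportLabels = supportLabels,
       queryLabels = queryLabels, classMap = as.integer(classMap))
}

#' Per-class mean feature vectors (class prototypes)
#'
#' @param features numeric matrix, one feature row per support sample.
#' @param labels episode-local integer labels \code{0..nWay-1}.
#' @param nWay number of episode classes; every class must be present.
#' @param classMap optional mapping from episode-local to dataset ids.
#' @return a [PrototypeSet-class] whose row m+1 is the arithmetic mean of
#'   the class-m support features.
#' @export
computePrototypes <- function(features, labels, nWay,
                              classMap = seq_len(nWay) - 1L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  proto <- matrix(0, nWay, ncol(features))
  for (m in seq_len(nWay) - 1L) {
    rows <- which(labels == m)
    if (!length(rows))
      stop(sprintf("episode class %d has no support samples", m))
    proto[m + 1L, ] <- colMeans(features[rows, , drop = FALSE])
  }
  new("PrototypeSet", prototypes = proto, classMap = as.integer(classMap))
}

#' Nearest-centroid classification of query features
#'
#' Class posterior \eqn{p(y = m \mid x) = \exp(-d_m) / \sum_{m'}
#' \exp(-d_{m'})} with \eqn{d_m} the squared Euclidean distance between the
#' query feature and prototype m. Predictions are the argmax, with ties
#' broken toward the smallest episode-local class id. Distances are shifted
#' by their row minimum before exponentiation, so the softmax is stable for
#' far-away prototypes.
#'
#' @param queryFeatures numeric matrix, one query feature per row.
#' @param prototypes a [PrototypeSet-class].
#' @return list with \code{prob} (rows summing to 1) and \code{pred}
#'   (0-based episode-local labels).
#' @export
classifyQueries <- function(queryFeatures, prototypes) {
  if (!is.matrix(queryFeatures)) queryFeatures <- matrix(queryFeatures, 1L)
  P <- prototypes@prototypes
  if (ncol(queryFeatures) != ncol(P))
    stop("query feature dimension does not match prototypes")
  if (any(!is.finite(queryFeatures)))
    stop("query features must be finite")
  # squared Euclidean distances via |x|^2 - 2 x.mu + |mu|^2
  d2 <- outer(rowSums(queryFeatures^2), rep(1, nrow(P))) -
    2 * queryFeatures %*% t(P) +
    outer(rep(1, nrow(queryFeatures)), rowSums(P^2))
  d2 <- pmax(d2, 0)
  logits <- -d2
  logits <- logits - apply(logits, 1L, max)
  E <- exp(logits)
  prob <- E / rowSums(E)
  pred <- max.col(prob, ties.method = "first") - 1L
  list(prob = prob, pred = pred)
}

#' Episodic top-1 accuracy
#'
#' @param predictions,trueLabels equal-length integer vectors.
#' @return fraction of matching entries.
#' @export
episodeAccuracy <- function(predictions, trueLabels) {
  if (length(predictions) != length(trueLabels))
    stop("predictions and trueLabels must have equal length")
  if (length(predictions) == 0L) stop("empty episode")
  mean(predictions == trueLabels)
}

#' Cumulative confusion matrix over episodes
#'
#' @param episodeResults list of lists with integer fields \code{pred} and
#'   \code{true} in the episode-local label space.
#' @param nWay common episode width.
#' @return integer matrix; entry (m, m') counts queries of true class m-1
#'   predicted as class m'-1, accumulated over episodes.
#' @export
cumulativeConfusion <- function(episodeResults, nWay) {
  conf <- matrix(0L, nWay, nWay,
                 dimnames = list(true = seq_len(nWay) - 1L,
                                 predicted = seq_len(nWay) - 1L))
  for (er in episodeResults) {
    if (max(er$true, er$pred) >= nWay || min(er$true, er$pred) < 0L)
      stop("episode labels exceed the shared nWay")
    for (i in seq_along(er$true))
      conf[er$true[i] + 1L, er$pred[i] + 1L] <-
        conf[er$true[i] + 1L, er$pred[i] + 1L] + 1L
  }
  conf
}

#' @keywords internal
evalSummary <- function(perEpisodeAcc, confusion, nWay, kShot, qQuery) {
  n <- length(perEpisodeAcc)
  s <- stats::sd(perEpisodeAcc)               # Bessel: n - 1 denominator
  new("EvalResult", perEpisodeAcc = perEpisodeAcc,
      meanAcc = mean(perEpisodeAcc), besselSD = s,
      halfWidth = 1.96 * s / sqrt(n), nEpisodes = as.integer(n),
      confusion = confusion, nWay = as.integer(nWay),
      kShot = as.integer(kShot), qQuery = as.integer(qQuery))
}

#' Episodic few-shot evaluation of a frozen encoder
#'
#' Embeds the dataset once with the frozen encoder, then runs
#' \code{nEpisodes} independent N-way K-shot episodes: per episode,
#' prototypes from the support features, nearest-centroid classification
#' of the queries, and top-1 accuracy. Reports the mean accuracy, Bessel
#' standard deviation, 95% confidence half-width \eqn{1.96 s/\sqrt{n}}, and
#' the cumulative confusion matrix.
#'
#' @param encoder a frozen [ConvEncoder-class].
#' @param dataset an [ImageSet-class] of novel classes.
#' @param nWay,kShot,qQuery episode geometry (defaults 5-way, Q = 15).
#' @param nEpisodes number of episodes (at least 2; 600 by default).
#' @param seed RNG seed for episode sampling.
#' @param features optional precomputed feature matrix (one row per
#'   dataset image), bypassing the encoder.
#' @return an [EvalResult-class].
#' @export
evaluateFewShot <- function(encoder, dataset, nWay = 5L, kShot = 5L,
                            qQuery = 15L, nEpisodes = 600L, seed = 1L,
                            features = NULL) {
  if (nEpisodes < 2L)
    stop("at least 2 episodes are required for the Bessel standard deviation")
  if (is.null(features))
    features <- embedImages(encoder, dataset)
  labels <- dataset@labels
  set.seed(as.integer(seed))
  acc <- numeric(nEpisodes)
  results <- vector("list", nEpisodes)
  for (ep in seq_len(nEpisodes)) {
    idx <- episodeIndices(labels, nWay, kShot, qQuery,
                          classNames = dataset@classNames)
    proto <- computePrototypes(features[idx$support, , drop = FALSE],
                               idx$supportLabels, nWay, idx$classMap)
    cls <- classifyQueries(features[idx$query, , drop = FALSE], proto)
    acc[ep] <- episodeAccuracy(cls$pred, idx$queryLabels)
    results[[ep]] <- list(pred = cls$pred, true = idx$queryLabels)
  }
  conf <- cumulativeConfusion(results, nWay)
  evalSummary(acc, conf, nWay, kShot, qQuery)
}

#' Format an evaluation result as "mean +/- halfwidth" in percent
#'
#' @param result an [EvalResult-class].
#' @return character scalar such as \code{"78.55 ± 0.81"}.
#' @export
formatAccuracy <- function(result) {
  sprintf("%.2f ± %.2f", 100 * result@meanAcc, 100 * result@halfWidth)
}
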
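# Independent brute-force oracles used to pin down the vectorized
# implementations. All are literal loop translations of the defining
# formulas and deliberately share no code with the package internals.

# Literal triple-loop supervised contrastive loss: for each anchor i,
# average -log softmax over its positives with coefficient 1/|P(i)|.
supConLossOracle <- function(Z, labels, tau) {
  n <- nrow(Z)
  nrm <- sqrt(rowSums(Z^2))
  total <- 0
  for (i in seq_len(n)) {
    positives <- setdiff(which(labels == labels[i]), i)
    if (!length(positives)) next
    anchorSum <- 0
    for (j in positives) {
      sij <- sum(Z[i, ] * Z[j, ]) / (nrm[i] * nrm[j])
      denom <- 0
      for (k in seq_len(n)) {
        if (k == i) next
        sik <- sum(Z[i, ] * Z[k, ]) / (nrm[i] * nrm[k])
        denom <- denom + exp(sik / tau)
      }
      anchorSum <- anchorSum + (-log(exp(sij / tau) / denom))
    }
    total <- total + anchorSum / length(positives)
  }
  total
}

# Self-supervised NT-Xent oracle on an interleaved two-view batch: the only
# positive of view i is its partner view.
ntXentOracle <- function(Z, tau) {
  n <- nrow(Z)
  nrm <- sqrt(rowSums(Z^2))
  partner <- function(i) if (i %% 2 == 1) i + 1L else i - 1L
  total <- 0
  for (i in seq_len(n)) {
    j <- partner(i)
    sij <- sum(Z[i, ] * Z[j, ]) / (nrm[i] * nrm[j])
    denom <- 0
    for (k in seq_len(n)) {
      if (k == i) next
      sik <- sum(Z[i, ] * Z[k, ]) / (nrm[i] * nrm[k])
      denom <- denom + exp(sik / tau)
    }
    total <- total - log(exp(sij / tau) / denom)
  }
  total
}

# Random unit-row embedding matrix for an interleaved two-view batch of
# nOrig originals drawn from nCls classes.
randomTwoViewEmbeddings <- function(nOrig, d, nCls = max(2L, nOrig %/% 2L)) {
  Z <- matrix(rnorm(2 * nOrig * d), 2 * nOrig, d)
  Z <- Z / sqrt(rowSums(Z^2))
  origLabels <- sample.int(nCls, nOrig, replace = TRUE) - 1L
  list(Z = Z, labels = rep(origLabels, each = 2L))
}

# Brute-force nearest-centroid pipeline: per-class feature means, squared
# Euclidean softmax, argmax with smallest-id tie break.
protoPipelineOracle <- function(supportF, supportL, queryF, queryL, nWay) {
  proto <- matrix(0, nWay, ncol(supportF))
  for (m in seq_len(nWay) - 1L)
    proto[m + 1L, ] <- colMeans(supportF[supportL == m, , drop = FALSE])
  preds <- integer(nrow(queryF))
  probs <- matrix(0, nrow(queryF), nWay)
  for (q in seq_len(nrow(queryF))) {
    d2 <- numeric(nWay)
    for (m in seq_len(nWay))
      d2[m] <- sum((queryF[q, ] - proto[m, ])^2)
    e <- exp(-d2)
    probs[q, ] <- e / sum(e)
    preds[q] <- which.max(probs[q, ]) - 1L
  }
  list(proto = proto, probs = probs, preds = preds,
       acc = sum(preds == queryL) / length(queryL))
}

# Tiny deterministic test image: smooth RGB gradient, values in [0, 1].
gradientImage <- function(h = 32L, w = h) {
  r <- matrix(seq(0, 1, length.out = h), h, w)
  g <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  b <- (r + g) / 2
  array(c(r, g, b), c(h, w, 3L))
}

# Small synthetic dataset shared by fixture-hungry tests (memoized).
.fixtureEnv <- new.env()
smallSyntheticDataset <- function() {
  if (is.null(.fixtureEnv$ds))
    .fixtureEnv$ds <- generateSyntheticDataset(
      syntheticDatasetConfig(nClasses = 5, perClass = 30, imageSize = 32,
                             seed = 404))
  .fixtureEnv$ds
}
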
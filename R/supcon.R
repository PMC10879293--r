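# Supervised contrastive loss (temperature-scaled cosine similarity over a
# two-view batch, label-aware positive sets, per-anchor averaging by
# 1/(2*N_y - 1)) and the phase-1 pre-training loop: SGD with momentum and
# weight decay under a warmup + three-segment cosine-annealing schedule.

#' Pairwise cosine similarity of embedding rows
#'
#' @param Z numeric matrix, one embedding per row.
#' @return symmetric matrix with entry (i, j) equal to
#'   \eqn{z_i^T z_j / (\|z_i\| \|z_j\|)}; entries lie in [-1, 1] and the
#'   diagonal is 1.
#' @examples
#' cosineSimilarityMatrix(rbind(c(1, 0), c(0, 1)))
#' @export
cosineSimilarityMatrix <- function(Z) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  if (nrow(Z) == 0L) stop("empty embedding matrix")
  if (any(!is.finite(Z))) stop("embeddings must be finite")
  nrm <- sqrt(rowSums(Z * Z))
  if (any(nrm < 1e-12)) stop("zero-norm embedding row")
  S <- tcrossprod(Z / nrm)
  pmin(pmax(S, -1), 1)
}

#' Supervised contrastive loss
#'
#' Computes, over a batch of embeddings \code{Z} with class labels, the
#' loss \deqn{L = \sum_i \frac{1}{|P(i)|} \sum_{j \in P(i)}
#'   -\log\frac{\exp(s_{ij}/\tau)}{\sum_{k \ne i}\exp(s_{ik}/\tau)}}
#' where \eqn{s_{ij}} is the cosine similarity and \eqn{P(i)} the set of
#' other batch members sharing anchor i's label (in a two-view batch of N
#' originals this set has \eqn{2 N_{y_i} - 1} members, with \eqn{N_{y_i}}
#' the number of originals labeled \eqn{y_i}). The per-anchor log-sum-exp
#' is computed with max subtraction, which keeps small temperatures (0.02)
#' stable.
#'
#' Anchors with no positive in the batch cannot arise from a valid
#' two-view batch (the partner view is always a positive); when handed
#' arbitrary labels such anchors contribute 0 and a warning is emitted.
#'
#' @param Z numeric matrix of embeddings, one row per view. Rows need not
#'   be unit norm for the loss value; the gradient assumes unit rows (the
#'   projection head's normalization supplies them during training).
#' @param labels integer class label per row.
#' @param tau positive temperature.
#' @param grad if \code{TRUE}, also return the gradient with respect to
#'   \code{Z} (unit rows assumed).
#' @return the loss (sum over anchors, non-negative) or, with
#'   \code{grad = TRUE}, \code{list(loss =, grad =)}.
#' @examples
#' u <- c(1, 0); v <- c(0, 1)
#' Z <- rbind(u, u, v, v)
#' supervisedContrastiveLoss(Z, c(0, 0, 1, 1), tau = 1)  # 4 * -log(e/(e+2))
#' @export
supervisedContrastiveLoss <- function(Z, labels, tau, grad = FALSE) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  if (tau <= 0) stop("temperature tau must be > 0")
  n <- nrow(Z)
  if (n < 2L) stop("at least two views are required")
  if (length(labels) != n) stop("one label per embedding row is required")
  S <- cosineSimilarityMatrix(Z)
  A <- S / tau
  diag(A) <- -Inf
  rowMax <- apply(A, 1L, max)
  E <- exp(A - rowMax)                     # diagonal underflows to 0
  lse <- rowMax + log(rowSums(E))
  posMask <- outer(labels, labels, "==")
  diag(posMask) <- FALSE
  nPos <- rowSums(posMask)
  if (any(nPos == 0L))
    warning("anchor(s) without positives contribute 0 to the loss")
  active <- nPos > 0L
  Apos <- A
  diag(Apos) <- 0                          # avoid -Inf * 0 in the mask product
  perAnchor <- numeric(n)
  perAnchor[active] <-
    (lse[active] * nPos[active] -
       rowSums((Apos * posMask)[active, , drop = FALSE])) / nPos[active]
  loss <- sum(perAnchor)
  if (!grad) return(loss)
  P <- E / rowSums(E)                      # softmax over k != i
  G <- P
  G[active, ] <- G[active, ] - posMask[active, , drop = FALSE] /
    nPos[active]
  G[!active, ] <- 0
  diag(G) <- 0
  dZ <- (G + t(G)) %*% Z / tau
  list(loss = loss, grad = dZ)
}

#' Self-supervised NT-Xent loss (reference reduction)
#'
#' The traditional self-supervised contrastive loss on an interleaved
#' two-view batch, where the only positive of each anchor is its partner
#' view. Equals [supervisedContrastiveLoss()] whenever all originals carry
#' distinct labels.
#'
#' @param Z embedding matrix with interleaved views (rows 2k-1, 2k paired).
#' @param tau positive temperature.
#' @return the loss summed over anchors.
#' @export
ntXentLoss <- function(Z, tau) {
  n <- nrow(Z)
  if (n %% 2L != 0L) stop("interleaved two-view batch required (even rows)")
  pairLabels <- rep(seq_len(n %/% 2L), each = 2L)
  supervisedContrastiveLoss(Z, pairLabels, tau)
}

#' Learning-rate schedule of the pre-training loop
#'
#' Linear warmup from \code{baseLR / 100} over \code{warmupEpochs}, then
#' either (default) cosine annealing restarted over three equal segments
#' whose peak learning rates are \code{baseLR * lrDecay^p} for segment
#' p = 0, 1, 2, or a plain step schedule multiplying by \code{lrDecay} at
#' each third of the remaining epochs.
#'
#' @param config a [TrainConfig-class].
#' @param epoch 1-based epoch index.
#' @return the learning rate used throughout that epoch.
#' @export
learningRate <- function(config, epoch) {
  wu <- config@warmupEpochs
  if (epoch <= wu) {
    lo <- config@baseLR / 100
    return(lo + (config@baseLR - lo) * (epoch - 1L) / max(1L, wu))
  }
  rest <- config@epochs - wu
  e <- epoch - wu - 1L                       # 0-based position after warmup
  segLen <- max(1L, ceiling(rest / 3))
  seg <- min(2L, e %/% segLen)
  peak <- config@baseLR * config@lrDecay^seg
  if (config@schedule == "step") return(peak)
  frac <- (e - seg * segLen) / segLen
  peak * 0.5 * (1 + cos(pi * frac))
}

#' @keywords internal
sgdUpdate <- function(params, grads, velocity, lr, momentum, weightDecay) {
  for (nm in names(grads)) {
    # weight decay on weight matrices only, not batch-norm scale/shift or
    # bias vectors (standard practice)
    g <- grads[[nm]]
    if (is.matrix(params[[nm]])) g <- g + weightDecay * params[[nm]]
    v <- momentum * velocity[[nm]] - lr * g
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, velocity = velocity)
}

#' Phase-1 supervised contrastive pre-training
#'
#' Trains an encoder and projection head on a labeled image dataset: each
#' step samples a minibatch of N originals, builds 2N interleaved augmented
#' views, encodes and projects them to unit-norm embeddings, computes the
#' supervised contrastive loss, and takes an SGD step (momentum + weight
#' decay) at the scheduled learning rate. The optimized objective is the
#' per-anchor mean (loss / 2N) so step sizes are comparable across batch
#' sizes; the trace records that mean. Incomplete final minibatches are
#' dropped. The projection head is returned for inspection but is not part
#' of the phase-2 contract.
#'
#' @param dataset an [ImageSet-class] with at least two classes.
#' @param config a [TrainConfig-class]; \code{config@augment@outputSize}
#'   fixes the encoder input size.
#' @param channels conv channels of the encoder.
#' @param projDim contrastive embedding dimension d_z.
#' @param verbose print a line per epoch.
#' @return list with \code{encoder} (a frozen [ConvEncoder-class]),
#'   \code{head} (the discarded [ProjectionHead-class]), and \code{trace}
#'   (data.frame epoch, step, lr, loss).
#' @export
pretrainEncoder <- function(dataset, config,
                            channels = c(16L, 32L, 64L, 64L),
                            projDim = 128L, verbose = FALSE) {
  validObject(config)
  nCls <- length(unique(dataset@labels))
  if (nCls < 2L)
    stop("pre-training requires at least two classes: with a single class ",
         "every pair is positive and the loss degenerates")
  n <- length(dataset)
  N <- config@batchSize
  if (n < N) stop("dataset smaller than one minibatch")
  size <- config@augment@outputSize
  set.seed(config@seed)
  encoder <- convEncoder(size, channels, seed = config@seed)
  head <- projectionHead(encoder@featureDim, outDim = projDim,
                         seed = config@seed + 1L)
  transform <- makeAugmentationPipeline(config@augment)
  velocity <- lapply(c(encoder@weights, head@weights), function(p) p * 0)
  stepsPerEpoch <- n %/% N
  trace <- data.frame(epoch = integer(0), step = integer(0),
                      lr = numeric(0), loss = numeric(0))
  set.seed(config@seed + 1000L)
  for (epoch in seq_len(config@epochs)) {
    lr <- learningRate(config, epoch)
    perm <- sample.int(n)
    for (step in seq_len(stepsPerEpoch)) {
      idx <- perm[((step - 1L) * N + 1L):(step * N)]
      batch <- buildTwoViewBatch(dataset@images[idx], transform,
                                 dataset@labels[idx])
      X <- stackImages(batch$views)
      fwd <- encoderForward(encoder, X, keepCache = TRUE, train = TRUE)
      encoder@bnStats <- fwd$bnStats
      prj <- projectionForward(head, fwd$h)
      lg <- supervisedContrastiveLoss(prj$z, batch$labels, config@tau,
                                      grad = TRUE)
      meanLoss <- lg$loss / (2L * N)
      dZ <- lg$grad / (2L * N)
      bk <- projectionBackward(head, dZ, prj$cache)
      encGrads <- encoderBackward(encoder, bk$dH, fwd$cache)
      upd <- sgdUpdate(c(encoder@weights, head@weights),
                       c(encGrads, bk$grads),
                       velocity, lr, config@momentum, config@weightDecay)
      velocity <- upd$velocity
      encoder@weights <- upd$params[names(encoder@weights)]
      head@weights <- upd$params[names(head@weights)]
      trace <- rbind(trace, data.frame(epoch = epoch, step = step,
                                       lr = lr, loss = meanLoss))
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  mean loss %.4f", epoch, lr,
                      mean(trace$loss[trace$epoch == epoch])))
  }
  list(encoder = freezeEncoder(encoder), head = head, trace = trace)
}
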
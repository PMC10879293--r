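# Vectorized neural-network primitives on (H, W, C, B) image batches.
# Convolutions are 3x3, stride 1, zero padding 1, lowered to a single BLAS
# matmul via im2col; each op returns the cache its backward pass needs.
# The im2col gather indices depend only on the batch geometry, so they are
# built once per (H, W, C, B) and memoized.

.im2colCache <- new.env(parent = emptyenv())

# Gather plan: M[(h,w,b), (o,c)] = Xp[h+dy, w+dx, c, b] over the 9 kernel
# offsets o = (dx, dy). Returns the HWB x 9C linear-index matrix into the
# padded array plus the per-column bases used by the backward scatter.
#' @keywords internal
im2colPlan <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  plan <- .im2colCache[[key]]
  if (!is.null(plan)) return(plan)
  Hp <- H + 2L; Wp <- W + 2L
  h <- rep(seq_len(H), times = W * B)
  w <- rep(rep(seq_len(W), each = H), times = B)
  b <- rep(seq_len(B), each = H * W)
  base <- h + Hp * (w - 1L) + (Hp * Wp * C) * (b - 1L)
  off <- integer(9L * C)
  k <- 0L
  for (cc in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    off[k] <- dy + Hp * dx + Hp * Wp * (cc - 1L)
  }
  idx <- outer(base, off, "+")
  plan <- list(idx = idx, base = base, off = off,
               dims = c(H, W, C, B), padDims = c(Hp, Wp, C, B))
  .im2colCache[[key]] <- plan
  plan
}

#' @keywords internal
conv3x3Forward <- function(X, K, b) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  stopifnot(nrow(K) == 9L * C)
  plan <- im2colPlan(H, W, C, B)
  Xp <- array(0, plan$padDims)
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  M <- Xp[plan$idx]
  dim(M) <- c(H * W * B, 9L * C)
  Y <- M %*% K + rep(b, each = H * W * B)      # (HWB, F)
  Fch <- ncol(K)
  dim(Y) <- c(H, W, B, Fch)
  list(out = aperm(Y, c(1L, 2L, 4L, 3L)),      # (H, W, F, B)
       cache = list(M = M, dims = d))
}

#' @keywords internal
conv3x3Backward <- function(dY, K, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Fch <- ncol(K)
  plan <- im2colPlan(H, W, C, B)
  dYm <- aperm(dY, c(1L, 2L, 4L, 3L))          # (H, W, B, F)
  dim(dYm) <- c(H * W * B, Fch)
  dK <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(K)                           # (HWB, 9C)
  dXp <- numeric(prod(plan$padDims))
  for (k in seq_along(plan$off)) {             # columns have unique targets
    tgt <- plan$base + plan$off[k]
    dXp[tgt] <- dXp[tgt] + dM[, k]
  }
  dim(dXp) <- plan$padDims
  list(dX = dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dK = dK, db = db)
}

#' @keywords internal
reluForward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

#' @keywords internal
reluBackward <- function(dY, mask) dY * mask

# 2x2 mean pooling, stride 2; H and W must be even.
#' @keywords internal
meanPool2Forward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); ie <- io + 1L
  jo <- seq(1L, W, 2L); je <- jo + 1L
  out <- (X[io, jo, , , drop = FALSE] + X[ie, jo, , , drop = FALSE] +
          X[io, je, , , drop = FALSE] + X[ie, je, , , drop = FALSE]) / 4
  list(out = out, cache = d)
}

#' @keywords internal
meanPool2Backward <- function(dY, dims) {
  H <- dims[1]; W <- dims[2]
  dX <- array(0, dims)
  io <- seq(1L, H, 2L); ie <- io + 1L
  jo <- seq(1L, W, 2L); je <- jo + 1L
  g <- dY / 4
  dX[io, jo, , ] <- g
  dX[ie, jo, , ] <- g
  dX[io, je, , ] <- g
  dX[ie, je, , ] <- g
  dX
}

# Global spatial mean pooling: (H, W, C, B) -> (B, C) feature matrix.
#' @keywords internal
globalMeanPoolForward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  h <- matrix(colMeans(matrix(X, H * W, C * B)), C, B)
  list(out = t(h), cache = d)
}

#' @keywords internal
globalMeanPoolBackward <- function(dH, dims) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]; B <- dims[4]
  g <- t(dH) / (H * W)                         # (C, B)
  dX <- array(rep(as.numeric(g), each = H * W), dims)
  dX
}

# Row-wise unit normalization y_i = x_i / ||x_i||, with backward
# dx = (dy - y <y, dy>) / ||x||.
#' @keywords internal
rowNormalizeForward <- function(X, eps = 1e-12) {
  nrm <- sqrt(rowSums(X * X))
  if (any(nrm < eps))
    stop("cannot unit-normalize a zero-norm row")
  Y <- X / nrm
  list(out = Y, cache = list(Y = Y, nrm = nrm))
}

#' @keywords internal
rowNormalizeBackward <- function(dY, cache) {
  Y <- cache$Y
  (dY - Y * rowSums(dY * Y)) / cache$nrm
}

#' @keywords internal
linearForward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2L, b, "+"), cache = X)
}

#' @keywords internal
linearBackward <- function(dY, W, X) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

#' @keywords internal
heInitMatrix <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Per-channel batch normalization over the (H, W, B) positions of an
# (H, W, C, B) activation array. Training mode uses batch statistics
# (biased variance, as is standard); evaluation mode uses running
# statistics, which keeps frozen-encoder embeddings deterministic.

#' @keywords internal
bnToMatrix <- function(X) {
  d <- dim(X)
  M <- aperm(X, c(1L, 2L, 4L, 3L))
  dim(M) <- c(d[1] * d[2] * d[4], d[3])
  M
}

#' @keywords internal
bnToArray <- function(M, d) {
  dim(M) <- c(d[1], d[2], d[4], d[3])
  aperm(M, c(1L, 2L, 4L, 3L))
}

#' @keywords internal
batchNormForward <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X)
  M <- bnToMatrix(X)
  m <- nrow(M)
  mu <- colMeans(M)
  xc <- M - rep(mu, each = m)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = m)
  Y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(out = bnToArray(Y, d),
       cache = list(xhat = xhat, istd = istd, dims = d, m = m),
       batchMean = mu, batchVar = v)
}

#' @keywords internal
batchNormBackward <- function(dY, gamma, cache) {
  m <- cache$m
  dYm <- bnToMatrix(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = m)
  dX <- (dxhat - rep(colSums(dxhat) / m, each = m) -
           xhat * rep(colSums(dxhat * xhat) / m, each = m)) *
    rep(cache$istd, each = m)
  list(dX = bnToArray(dX, cache$dims), dgamma = dgamma, dbeta = dbeta)
}

#' @keywords internal
batchNormEval <- function(X, gamma, beta, runMean, runVar, eps = 1e-5) {
  d <- dim(X)
  M <- bnToMatrix(X)
  m <- nrow(M)
  scale <- gamma / sqrt(runVar + eps)
  Y <- M * rep(scale, each = m) + rep(beta - runMean * scale, each = m)
  bnToArray(Y, d)
}
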
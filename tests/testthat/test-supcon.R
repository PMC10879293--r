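# Supervised contrastive loss, cosine similarity, projection head, and the
# learning-rate schedule.

test_that("cosine similarity matrix matches a scalar double-loop oracle", {
  set.seed(101)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  Z <- Z / sqrt(rowSums(Z^2))
  S <- cosineSimilarityMatrix(Z)
  expect_equal(dim(S), c(6L, 6L))
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(S >= -1 & S <= 1))
  expect_equal(diag(S), rep(1, 6), tolerance = 1e-9)
  for (i in 1:6) for (j in 1:6) {
    expected <- sum(Z[i, ] * Z[j, ]) /
      (sqrt(sum(Z[i, ]^2)) * sqrt(sum(Z[j, ]^2)))
    expect_lt(abs(S[i, j] - expected), 1e-9)
  }
})

test_that("cosine similarity handles identical and orthogonal unit vectors", {
  expect_equal(cosineSimilarityMatrix(rbind(c(1, 0), c(1, 0))),
               matrix(1, 2, 2))
  S <- cosineSimilarityMatrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(S, diag(2))
  expect_error(cosineSimilarityMatrix(rbind(c(0, 0), c(1, 0))), "zero-norm")
})

test_that("loss is zero for a singleton two-view batch", {
  set.seed(5)
  z <- rnorm(8); z <- z / sqrt(sum(z^2))
  w <- rnorm(8); w <- w / sqrt(sum(w^2))
  for (tau in c(0.02, 0.1, 1)) {
    expect_equal(supervisedContrastiveLoss(rbind(z, w), c(3L, 3L), tau), 0,
                 tolerance = 1e-12)
  }
})

test_that("orthogonal two-class batch at tau = 1 gives the closed form", {
  u <- c(1, 0); v <- c(0, 1)
  Z <- rbind(u, u, v, v)
  perAnchor <- -log(exp(1) / (exp(1) + 2))
  got <- supervisedContrastiveLoss(Z, c(0L, 0L, 1L, 1L), tau = 1)
  expect_equal(got, 4 * perAnchor, tolerance = 1e-10)
  expect_equal(got, 2.2056, tolerance = 1e-4)
})

test_that("vectorized loss equals the triple-loop oracle on random batches", {
  set.seed(202)
  for (r in 1:25) {
    nOrig <- sample(2:16, 1)
    d <- sample(2:8, 1)
    tau <- sample(c(0.02, 0.1, 0.2), 1)
    b <- randomTwoViewEmbeddings(nOrig, d)
    got <- supervisedContrastiveLoss(b$Z, b$labels, tau)
    expect_lt(abs(got - supConLossOracle(b$Z, b$labels, tau)), 1e-6)
    expect_true(is.finite(got) && got >= 0)
  }
})

test_that("loss is invariant under joint row/label permutation", {
  set.seed(303)
  for (r in 1:10) {
    b <- randomTwoViewEmbeddings(sample(3:10, 1), 6)
    perm <- sample(nrow(b$Z))
    expect_equal(supervisedContrastiveLoss(b$Z, b$labels, 0.1),
                 supervisedContrastiveLoss(b$Z[perm, ], b$labels[perm], 0.1),
                 tolerance = 1e-6)
  }
})

test_that("all-distinct labels reduce the loss to self-supervised NT-Xent", {
  set.seed(404)
  for (r in 1:10) {
    nOrig <- sample(2:12, 1)
    Z <- matrix(rnorm(2 * nOrig * 5), 2 * nOrig, 5)
    Z <- Z / sqrt(rowSums(Z^2))
    labels <- rep(seq_len(nOrig) - 1L, each = 2L)
    expect_equal(supervisedContrastiveLoss(Z, labels, 0.1),
                 ntXentOracle(Z, 0.1), tolerance = 1e-6)
    expect_equal(ntXentLoss(Z, 0.1), ntXentOracle(Z, 0.1),
                 tolerance = 1e-6)
  }
})

test_that("invalid inputs are rejected and positive-free anchors warn", {
  Z <- diag(4)
  expect_error(supervisedContrastiveLoss(Z, rep(0L, 4), tau = 0), "tau")
  expect_error(supervisedContrastiveLoss(Z[1, , drop = FALSE], 0L, 0.1))
  expect_warning(
    supervisedContrastiveLoss(Z, c(0L, 0L, 1L, 2L), 0.1),
    "without positives")
})

test_that("analytic loss gradient matches finite differences", {
  # the gradient is defined for unit rows, where sim reduces to the plain
  # dot product; the finite-difference oracle therefore evaluates the loss
  # with dot-product similarities at freely perturbed coordinates
  dotLoss <- function(Z, labels, tau) {
    n <- nrow(Z); total <- 0
    for (i in seq_len(n)) {
      positives <- setdiff(which(labels == labels[i]), i)
      denom <- sum(exp((Z[-i, , drop = FALSE] %*% Z[i, ]) / tau))
      for (j in positives)
        total <- total +
          (-log(exp(sum(Z[i, ] * Z[j, ]) / tau) / denom)) / length(positives)
    }
    total
  }
  set.seed(505)
  b <- randomTwoViewEmbeddings(4, 5, nCls = 2)
  lg <- supervisedContrastiveLoss(b$Z, b$labels, 0.1, grad = TRUE)
  expect_equal(lg$loss, dotLoss(b$Z, b$labels, 0.1), tolerance = 1e-8)
  eps <- 1e-6
  for (probe in 1:8) {
    i <- sample(nrow(b$Z), 1); j <- sample(ncol(b$Z), 1)
    Zp <- b$Z; Zp[i, j] <- Zp[i, j] + eps
    Zm <- b$Z; Zm[i, j] <- Zm[i, j] - eps
    num <- (dotLoss(Zp, b$labels, 0.1) - dotLoss(Zm, b$labels, 0.1)) /
      (2 * eps)
    expect_lt(abs(lg$grad[i, j] - num), 1e-4)
  }
})

test_that("loss stays finite and stable across the temperature sweep", {
  set.seed(606)
  b <- randomTwoViewEmbeddings(16, 8, nCls = 4)
  for (tau in c(0.02, 0.05, 0.1, 0.2)) {
    v <- supervisedContrastiveLoss(b$Z, b$labels, tau)
    expect_true(is.finite(v))
    expect_gte(v, 0)
  }
})

test_that("projection head outputs unit rows of the configured dimension", {
  head <- projectionHead(8L, outDim = 4L, seed = 9)
  h <- matrix(rnorm(10 * 8), 10, 8)
  z <- projectFeatures(head, h)
  expect_equal(dim(z), c(10L, 4L))
  expect_equal(sqrt(rowSums(z^2)), rep(1, 10), tolerance = 1e-5)
  expect_identical(z, projectFeatures(head, h))     # frozen determinism
  expect_error(projectFeatures(head, matrix(0, 2, 5)), "dimension")
})

test_that("learning-rate schedule warms up then anneals in three segments", {
  cfg <- trainConfig(batchSize = 4, epochs = 70L, warmupEpochs = 10L,
                     baseLR = 0.05, lrDecay = 0.1, seed = 1,
                     augment = augmentationSpec("A", outputSize = 16))
  lrs <- vapply(1:70, function(e) learningRate(cfg, e), 0)
  expect_equal(lrs[1], 0.05 / 100)
  expect_lt(lrs[5], lrs[10])                      # linear ramp
  expect_equal(lrs[11], 0.05)                     # first segment peak
  expect_equal(lrs[31], 0.05 * 0.1)               # second segment peak
  expect_equal(lrs[51], 0.05 * 0.01)              # third segment peak
  expect_true(all(diff(lrs[11:30]) < 0))          # cosine decay within segment
  stepCfg <- trainConfig(batchSize = 4, epochs = 70L, warmupEpochs = 10L,
                         baseLR = 0.05, lrDecay = 0.1, schedule = "step",
                         seed = 1,
                         augment = augmentationSpec("A", outputSize = 16))
  expect_equal(vapply(11:30, function(e) learningRate(stepCfg, e), 0),
               rep(0.05, 20))
})
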
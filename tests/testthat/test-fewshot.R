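# Episodic sampling, prototypes, nearest-centroid classification, and the
# evaluation statistics.

test_that("episodes have the requested geometry and disjoint support/query", {
  ds <- smallSyntheticDataset()
  set.seed(31)
  ep <- sampleEpisode(ds, nWay = 5, kShot = 5, qQuery = 15)
  expect_s4_class(ep, "Episode")
  expect_length(ep@support, 25L)
  expect_length(ep@query, 75L)
  expect_length(intersect(ep@support@sourceIds, ep@query@sourceIds), 0L)
  for (m in 0:4) {
    expect_equal(sum(imageLabels(ep@support) == m), 5L)
    expect_equal(sum(imageLabels(ep@query) == m), 15L)
  }
  expect_true(all(ep@classMap %in% (seq_len(nClasses(ds)) - 1L)))
})

test_that("episode sampling errors name the offending constraint", {
  ds <- smallSyntheticDataset()
  expect_error(sampleEpisode(ds, nWay = 6, kShot = 1), "6")
  expect_error(sampleEpisode(ds, nWay = 2, kShot = 16, qQuery = 15),
               "synthetic_class")   # 16 + 15 > 30 images per class
})

test_that("prototypes are per-class means, matching a loop oracle", {
  set.seed(32)
  feats <- matrix(rnorm(30 * 4), 30, 4)
  labels <- rep(0:2, each = 10)
  proto <- computePrototypes(feats, labels, 3)
  for (m in 0:2) {
    manual <- colMeans(feats[labels == m, , drop = FALSE])
    expect_lt(max(abs(proto@prototypes[m + 1, ] - manual)), 1e-9)
  }
  expect_equal(computePrototypes(rbind(c(0, 0), c(2, 2)), c(0L, 0L), 1)@prototypes[1, ],
               c(1, 1))
  single <- matrix(c(3, 4), 1)
  expect_equal(computePrototypes(single, 0L, 1)@prototypes[1, ], c(3, 4))
  expect_error(computePrototypes(feats, labels, 4), "no support")
})

test_that("classification posterior follows the squared-Euclidean softmax", {
  proto <- new("PrototypeSet", prototypes = rbind(c(1, 0), c(0, 2)),
               classMap = c(0L, 1L))
  out <- classifyQueries(matrix(c(0, 0), 1), proto)
  # d = (1, 4); p1 = e^-1 / (e^-1 + e^-4)
  expect_equal(out$prob[1, 1], exp(-1) / (exp(-1) + exp(-4)),
               tolerance = 1e-12)
  expect_equal(out$prob[1, 1], 0.9526, tolerance = 1e-4)
  expect_equal(out$pred, 0L)

  nearDelta <- new("PrototypeSet",
                   prototypes = rbind(c(0, 0), c(10, 0), c(0, 10)),
                   classMap = 0:2)
  out2 <- classifyQueries(matrix(c(0, 0), 1), nearDelta)
  expect_gt(out2$prob[1, 1], 0.999)

  tie <- new("PrototypeSet", prototypes = rbind(c(1, 0), c(-1, 0)),
             classMap = c(0L, 1L))
  out3 <- classifyQueries(matrix(c(0, 0), 1), tie)
  expect_equal(out3$prob[1, ], c(0.5, 0.5))
  expect_equal(out3$pred, 0L)                 # tie broken to smallest id
})

test_that("posteriors normalize and argmax equals the nearest prototype", {
  set.seed(33)
  proto <- new("PrototypeSet", prototypes = matrix(rnorm(5 * 6), 5, 6),
               classMap = 0:4)
  q <- matrix(rnorm(40 * 6), 40, 6)
  out <- classifyQueries(q, proto)
  expect_equal(rowSums(out$prob), rep(1, 40), tolerance = 1e-9)
  for (i in 1:40) {
    d2 <- colSums((t(proto@prototypes) - q[i, ])^2)
    expect_equal(out$pred[i], which.min(d2) - 1L)
  }
  expect_error(classifyQueries(matrix(NA_real_, 1, 6), proto), "finite")
  expect_error(classifyQueries(matrix(0, 1, 3), proto), "dimension")
})

test_that("episode accuracy is the matching fraction", {
  expect_equal(episodeAccuracy(c(1L, 1L), c(1L, 1L)), 1.0)
  expect_equal(episodeAccuracy(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L)), 0.75)
  set.seed(34)
  p <- sample(0:4, 100, replace = TRUE)
  y <- sample(0:4, 100, replace = TRUE)
  expect_equal(episodeAccuracy(p, y), sum(p == y) / 100)
  expect_error(episodeAccuracy(1L, c(1L, 2L)), "length")
})

test_that("evaluation statistics implement the Bessel CI arithmetic", {
  acc <- c(0.8, 1.0, 0.6)
  conf <- matrix(c(36L, 0L, 0L, 36L), 2, 2)   # consistent dummy confusion
  res <- SupConFewShot:::evalSummary(acc, conf, nWay = 2, kShot = 1,
                                     qQuery = 12L)   # 3 episodes x 12 = 36
  expect_equal(res@meanAcc, 0.8)
  expect_equal(res@besselSD, 0.2)
  expect_equal(res@halfWidth, 1.96 * 0.2 / sqrt(3), tolerance = 1e-12)
  expect_equal(res@halfWidth, 0.2263, tolerance = 1e-4)
})

test_that("cumulative confusion accumulates counts and conserves totals", {
  eps <- list(
    list(true = c(0L, 0L, 1L, 1L), pred = c(0L, 1L, 1L, 1L)),
    list(true = c(0L, 0L, 1L, 1L), pred = c(0L, 0L, 0L, 1L))
  )
  conf <- cumulativeConfusion(eps, 2)
  expect_equal(unname(conf), rbind(c(3L, 1L), c(1L, 3L)))
  expect_equal(sum(conf), 8L)
  expect_error(cumulativeConfusion(list(list(true = 2L, pred = 0L)), 2),
               "nWay")
})

test_that("a class-separating encoder yields perfect, zero-variance results", {
  ds <- smallSyntheticDataset()
  # features = one-hot class indicator: distinct constant vector per class
  feats <- diag(5)[imageLabels(ds) + 1L, ]
  enc <- freezeEncoder(convEncoder(32, seed = 1))
  res <- evaluateFewShot(enc, ds, nWay = 5, kShot = 1, qQuery = 5,
                         nEpisodes = 20, seed = 9, features = feats)
  expect_equal(res@meanAcc, 1.0)
  expect_equal(res@besselSD, 0.0)
  expect_equal(res@halfWidth, 0.0)
  expect_equal(unname(diag(res@confusion)), rep(100L, 5))
  expect_equal(sum(res@confusion), 20L * 5L * 5L)
})

test_that("evaluation is reproducible under a fixed seed", {
  ds <- smallSyntheticDataset()
  enc <- freezeEncoder(convEncoder(32, c(4L, 8L, 8L, 8L), seed = 2))
  f <- embedImages(enc, ds)
  r1 <- evaluateFewShot(enc, ds, 3, 2, 4, 10, seed = 55, features = f)
  r2 <- evaluateFewShot(enc, ds, 3, 2, 4, 10, seed = 55, features = f)
  expect_identical(r1@perEpisodeAcc, r2@perEpisodeAcc)
  expect_identical(r1@confusion, r2@confusion)
  expect_error(evaluateFewShot(enc, ds, 3, 2, 4, nEpisodes = 1, seed = 1),
               "2 episodes")
})

test_that("full episode pipeline agrees with a brute-force implementation", {
  set.seed(36)
  for (r in 1:5) {
    nWay <- sample(2:4, 1)
    supportF <- matrix(rnorm(nWay * 5 * 4), nWay * 5, 4)
    supportL <- rep(seq_len(nWay) - 1L, each = 5)
    queryF <- matrix(rnorm(nWay * 7 * 4), nWay * 7, 4)
    queryL <- rep(seq_len(nWay) - 1L, each = 7)
    oracle <- protoPipelineOracle(supportF, supportL, queryF, queryL, nWay)
    proto <- computePrototypes(supportF, supportL, nWay)
    cls <- classifyQueries(queryF, proto)
    expect_lt(max(abs(proto@prototypes - oracle$proto)), 1e-9)
    expect_lt(max(abs(cls$prob - oracle$probs)), 1e-9)
    expect_identical(cls$pred, oracle$preds)
    expect_equal(episodeAccuracy(cls$pred, queryL), oracle$acc)
  }
})

test_that("accuracy formatting matches the two-decimal percent style", {
  res <- SupConFewShot:::evalSummary(c(0.78, 0.791), matrix(4L, 1, 1),
                                     nWay = 1, kShot = 1, qQuery = 2)
  expect_match(formatAccuracy(res), "^78\\.55 ± 1\\.08$")
})
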
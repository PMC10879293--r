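# Encoder construction, the frozen-embedding contract, and the correctness
# of the hand-rolled forward/backward passes.

test_that("encoder features are unit-norm and deterministic when frozen", {
  enc <- freezeEncoder(convEncoder(32, c(4L, 8L, 8L, 8L), seed = 21))
  imgs <- lapply(1:6, function(i) {
    set.seed(i); array(runif(32 * 32 * 3), c(32, 32, 3))
  })
  f1 <- embedImages(enc, imgs)
  f2 <- embedImages(enc, imgs)
  expect_identical(f1, f2)
  expect_equal(sqrt(rowSums(f1^2)), rep(1, 6), tolerance = 1e-5)
  expect_equal(ncol(f1), 8L)
})

test_that("embedding is batch-equivariant (matches one-at-a-time oracle)", {
  enc <- freezeEncoder(convEncoder(32, c(4L, 8L, 8L, 8L), seed = 22))
  imgs <- lapply(1:5, function(i) {
    set.seed(100 + i); array(runif(32 * 32 * 3), c(32, 32, 3))
  })
  batch <- embedImages(enc, imgs)
  oneAtATime <- t(vapply(imgs, function(im) embedImages(enc, im)[1, ],
                         numeric(8)))
  expect_equal(batch, oneAtATime, tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(embedImages(enc, imgs[perm]), batch[perm, ],
               tolerance = 1e-12)
})

test_that("an unfrozen encoder is rejected by the phase-2 contract", {
  enc <- convEncoder(32, c(4L, 8L, 8L, 8L), seed = 23)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_error(embedImages(enc, img), "frozen")
  expect_false(isFrozen(enc))
  expect_true(isFrozen(freezeEncoder(enc)))
})

test_that("images of other sizes are resized before embedding", {
  enc <- freezeEncoder(convEncoder(32, c(4L, 8L, 8L, 8L), seed = 24))
  big <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f <- embedImages(enc, big)
  expect_equal(dim(f), c(1L, 8L))
  expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-5)
})

test_that("backpropagated gradients match finite differences end to end", {
  set.seed(42)
  enc <- convEncoder(16, c(4L, 6L, 6L, 6L), seed = 3)
  head <- projectionHead(6L, outDim = 4L, seed = 4)
  X <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  labels <- c(0L, 0L, 1L, 1L)
  tau <- 0.1
  lossOf <- function(encW, headW) {
    e <- enc; e@weights <- encW
    hd <- head; hd@weights <- headW
    fwd <- SupConFewShot:::encoderForward(e, X, train = TRUE)
    z <- SupConFewShot:::projectionForward(hd, fwd$h)$z
    supervisedContrastiveLoss(z, labels, tau)
  }
  fwd <- SupConFewShot:::encoderForward(enc, X, keepCache = TRUE,
                                        train = TRUE)
  prj <- SupConFewShot:::projectionForward(head, fwd$h)
  lg <- supervisedContrastiveLoss(prj$z, labels, tau, grad = TRUE)
  bk <- SupConFewShot:::projectionBackward(head, lg$grad, prj$cache)
  eg <- SupConFewShot:::encoderBackward(enc, bk$dH, fwd$cache)
  eps <- 1e-6
  set.seed(7)
  for (nm in names(enc@weights)) {
    idx <- sample(length(enc@weights[[nm]]), 2)
    for (ix in idx) {
      up <- enc@weights; up[[nm]][ix] <- up[[nm]][ix] + eps
      dn <- enc@weights; dn[[nm]][ix] <- dn[[nm]][ix] - eps
      num <- (lossOf(up, head@weights) - lossOf(dn, head@weights)) / (2 * eps)
      expect_lt(abs(num - eg[[nm]][ix]) / max(1, abs(num)), 1e-4)
    }
  }
  for (nm in names(head@weights)) {
    ix <- sample(length(head@weights[[nm]]), 1)
    up <- head@weights; up[[nm]][ix] <- up[[nm]][ix] + eps
    dn <- head@weights; dn[[nm]][ix] <- dn[[nm]][ix] - eps
    num <- (lossOf(enc@weights, up) - lossOf(enc@weights, dn)) / (2 * eps)
    expect_lt(abs(num - bk$grads[[nm]][ix]) / max(1, abs(num)), 1e-4)
  }
})

test_that("checkpoints round-trip the encoder and write a JSON sidecar", {
  enc <- freezeEncoder(convEncoder(32, c(4L, 8L, 8L, 8L), seed = 25))
  path <- withr::local_tempfile(fileext = ".rds")
  cfg <- trainConfig(batchSize = 4, epochs = 2, seed = 1,
                     augment = augmentationSpec("AB", outputSize = 32))
  saveCheckpoint(enc, path, config = cfg, datasetFingerprint = "test",
                 finalLoss = 1.23)
  expect_true(file.exists(paste0(path, ".json")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$finalLoss, 1.23)
  expect_equal(sidecar$train$augment, "AB")
  back <- loadCheckpoint(path)
  expect_true(isFrozen(back))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(embedImages(back, img), embedImages(enc, img))
})
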
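test_that("segmentation loss vanishes at a one-hot-perfect prediction", {
  tg <- matrix(sample(0:4, 100, replace = TRUE), 10, 10)
  probs <- array(1e-7, c(10, 10, 5))
  for (k in 0:4) probs[, , k + 1][tg == k] <- 1 - 4e-7
  expect_lt(segLoss(probs, tg), 1e-3)
})

test_that("uniform two-class prediction gives the log-2 cross-entropy", {
  tg <- matrix(c(0L, 1L), 4, 4)
  probs <- array(0.5, c(4, 4, 2))
  n <- 16
  ng <- colSums(outer(as.integer(tg), 0:1, "=="))
  # independent direct evaluation of CE + soft-DICE for this input
  diceExp <- 1 - mean((2 * 0.5 * ng + 1) / (0.5 * n + ng + 1))
  expect_equal(segLoss(probs, tg), log(2) + diceExp, tolerance = 1e-12)
})

test_that("all mass on the wrong class drives DICE to 1 per class", {
  tg <- matrix(0L, 5, 5)
  probs <- array(0, c(5, 5, 2))
  probs[, , 2] <- 1
  eps <- 1e-9
  val <- segLoss(probs, tg, diceEpsilon = eps)
  ce <- -log(1e-6)  # clamped
  expect_equal(val - ce, 1, tolerance = 1e-6)
})

test_that("offset loss is a masked mean L1", {
  H <- 6; W <- 6
  tgt <- array(0, c(H, W, 2))
  prd <- tgt
  mask <- matrix(FALSE, H, W)
  expect_equal(offsetLoss(prd, tgt, mask), 0)  # empty foreground
  mask[3, 3] <- TRUE
  prd[3, 3, ] <- c(1, -1)
  expect_equal(offsetLoss(prd, tgt, mask), 2)  # |1| + |-1|
  # garbage restricted to background pixels never changes the loss
  for (i in 1:10) {
    junk <- prd
    bg <- which(!mask)
    junk[, , 1][bg] <- rnorm(length(bg), 0, 100)
    junk[, , 2][bg] <- rnorm(length(bg), 0, 100)
    expect_identical(offsetLoss(junk, tgt, mask),
                     offsetLoss(prd, tgt, mask))
  }
})

test_that("centroid focal loss matches direct single-pixel evaluation", {
  # positive pixel, yhat = 0.5, alpha = 2: -(1-0.5)^2 log 0.5
  expect_equal(centroidLoss(matrix(0.5), matrix(1), 1),
               -(0.5)^2 * log(0.5), tolerance = 1e-12)
  # soft negative at the Gaussian tail one sigma out
  y <- exp(-1 / 2)
  expect_equal(centroidLoss(matrix(0.5), matrix(y), 1),
               -(1 - y)^4 * 0.5^2 * log(0.5), tolerance = 1e-12)
  # binary target predicted exactly (clamped) -> ~0
  tgt <- matrix(0, 8, 8)
  tgt[4, 5] <- 1
  pred <- pmin(pmax(tgt, 1e-6), 1 - 1e-6)
  expect_lt(centroidLoss(pred, tgt, 1), 1e-3)
})

test_that("alpha = 0 focal on binary targets reduces to binary CE", {
  set.seed(4)
  tgt <- matrix(rbinom(64, 1, 0.2), 8, 8)
  pred <- matrix(runif(64, 0.05, 0.95), 8, 8)
  got <- centroidLoss(pred, tgt, nInstances = 3, alpha = 0, beta = 5)
  # independent plain binary cross-entropy, summed and scaled by 1/N
  ce <- -sum(ifelse(tgt == 1, log(pred), log(1 - pred))) / 3
  expect_equal(got, ce, tolerance = 1e-9)
})

test_that("type loss is weighted cross-entropy over instances", {
  p <- rep(1 / 7, 7)
  expect_equal(typeLoss(p, 3L), log(7), tolerance = 1e-12)
  sure <- c(1e-9, 1 - 6e-9, rep(1e-9, 5))
  expect_lt(typeLoss(sure, 2L), 1e-6)
  w <- classWeightsFromCounts(c(10, 5))
  expect_equal(w, c(2 / 3, 4 / 3))
  expect_equal(typeLoss(c(0.5, 0.5), 1L, w), -w[1] * log(0.5))
  # unit weights equal unweighted CE
  set.seed(1)
  P <- matrix(runif(21), 3, 7)
  P <- P / rowSums(P)
  cls <- c(2L, 7L, 1L)
  expect_equal(typeLoss(P, cls, rep(1, 7)), typeLoss(P, cls))
  expect_error(typeLoss(p, 9L), "unknown class")
})

test_that("the joint objective is a gamma-weighted sum", {
  expect_equal(jointLoss(1, 1, 1, 1, gamma = 10), 13)
  expect_equal(jointLoss(0, 0, 0, 0), 0)
  expect_equal(lossConfig()$gamma, 10)
  expect_error(jointLoss(Inf, 0, 0, 0))
})

test_that("losses are non-negative and vanish at the truth on random scenes", {
  cfg <- synthConfig()
  for (seed in seq(1, 40, by = 2)) {
    sc <- generateScene(cfg, seed = seed)
    tb <- buildTargets(sc, sigma = 2.5)
    nP <- 5L
    probs <- array(1e-7, c(64, 80, nP))
    for (k in 0:4) probs[, , k + 1][partTarget(tb) == k] <- 1 - 4e-7
    ls <- segLoss(probs, partTarget(tb))
    lo <- offsetLoss(offsetTarget(tb), offsetTarget(tb),
                     foregroundMask(tb))
    peak <- (heatmapTarget(tb) >= 1 - 1e-12) * 1
    lc <- centroidLoss(pmin(pmax(peak, 1e-6), 1 - 1e-6),
                       heatmapTarget(tb), nrow(centroidList(tb)))
    expect_gte(ls, 0)
    expect_gte(lo, 0)
    expect_gte(lc, -1e-12)
    expect_lt(ls, 1e-3)
    expect_equal(lo, 0)
    expect_lt(lc, 1e-3)
  }
})
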
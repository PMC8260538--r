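test_that("frameMIoU follows the present-in-ground-truth protocol", {
  gt <- matrix(0L, 6, 6)
  gt[2:3, 2:3] <- 1L
  gt[5, 5] <- 2L
  expect_equal(frameMIoU(gt, gt), 1)
  # 2x2 square of class 1 shifted one column: IoU = 2/6
  pred <- matrix(0L, 6, 6)
  pred[2:3, 3:4] <- 1L
  gt1 <- matrix(0L, 6, 6)
  gt1[2:3, 2:3] <- 1L
  expect_equal(frameMIoU(pred, gt1), 2 / 6)
  # a class absent from GT but predicted is excluded from the mean
  predExtra <- gt
  predExtra[1, 1] <- 3L
  expect_equal(frameMIoU(predExtra, gt), 1)
  # no instrument present: undefined
  expect_true(is.na(frameMIoU(matrix(1L, 3, 3), matrix(0L, 3, 3))))
  # symmetric in its arguments
  set.seed(40)
  a <- matrix(sample(0:3, 64, TRUE), 8, 8)
  b <- matrix(sample(0:3, 64, TRUE), 8, 8)
  onlyShared <- function(x, y) {
    # symmetric comparison needs identical present-label sets
    x[!x %in% intersect(unique(x), unique(y))] <- 0L
    x
  }
  a2 <- onlyShared(a, b); b2 <- onlyShared(b, a)
  expect_equal(frameMIoU(a2, b2), frameMIoU(b2, a2))
  expect_error(frameMIoU(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
})

test_that("datasetMIoU averages only frames with a present label", {
  full <- matrix(1L, 4, 4)
  half <- matrix(0L, 4, 4); half[, 1:2] <- 1L
  empty <- matrix(0L, 4, 4)
  preds <- list(full, half, full)
  gts <- list(full, full, empty)   # scores 1.0, 0.5, absent
  expect_equal(datasetMIoU(preds, gts), 0.75)
  expect_equal(datasetMIoU(list(full), list(full)), 1)
  expect_error(datasetMIoU(list(full), list(empty)), "no frame")
  # order invariance
  expect_equal(datasetMIoU(rev(preds), rev(gts)), 0.75)
})

test_that("maskMAP scores perfect, near-miss and wrong-class cases", {
  mk <- function(cells, n = 30) {
    m <- matrix(FALSE, 1, n)
    m[cells] <- TRUE
    m
  }
  gtA <- list(mask = mk(1:15), class = 1L, frame = "f1")
  # identical prediction: mAP 1
  p <- list(mask = mk(1:15), class = 1L, score = 0.9, frame = "f1")
  expect_equal(maskMAP(list(p), list(gtA))$mAP, 1)
  # IoU exactly 0.55 (|I|=11, |U|=20): TP at 0.50 and 0.55 only -> 2/10
  p2 <- list(mask = mk(5:20), class = 1L, score = 0.9, frame = "f1")
  expect_equal(sum(p2$mask & gtA$mask) / sum(p2$mask | gtA$mask), 0.55)
  expect_equal(maskMAP(list(p2), list(gtA))$mAP, 0.2)
  # wrong class: 0
  p3 <- list(mask = mk(1:15), class = 2L, score = 0.9, frame = "f1")
  expect_equal(maskMAP(list(p3), list(gtA))$mAP, 0)
  # same-class prediction in another frame never matches
  p4 <- list(mask = mk(1:15), class = 1L, score = 0.9, frame = "f2")
  expect_equal(maskMAP(list(p4), list(gtA))$mAP, 0)
})

test_that("maskMAP is monotone as the threshold set shifts upward", {
  set.seed(41)
  preds <- list(); gts <- list()
  for (f in 1:4) {
    g <- matrix(runif(100) < 0.3, 10, 10)
    noise <- matrix(runif(100) < 0.1, 10, 10)
    preds[[f]] <- list(mask = xor(g, noise & g), class = 1L,
                       score = runif(1), frame = paste0("f", f))
    gts[[f]] <- list(mask = g, class = 1L, frame = paste0("f", f))
  }
  lo <- maskMAP(preds, gts, thresholds = seq(0.3, 0.75, by = 0.05))$mAP
  hi <- maskMAP(preds, gts, thresholds = seq(0.5, 0.95, by = 0.05))$mAP
  expect_gte(lo, hi)
})

test_that("maskMAP agrees with the brute-force matcher on small cases", {
  set.seed(42)
  for (rep in 1:12) {
    preds <- list(); gts <- list()
    nP <- sample(1:3, 1); nG <- sample(1:3, 1)
    for (i in seq_len(nG)) {
      m <- matrix(FALSE, 8, 8)
      r <- sample(1:5, 1); c <- sample(1:5, 1)
      m[r:(r + 2), c:(c + 2)] <- TRUE
      gts[[i]] <- list(mask = m, class = sample(1:2, 1), frame = "f")
    }
    for (i in seq_len(nP)) {
      m <- matrix(FALSE, 8, 8)
      r <- sample(1:5, 1); c <- sample(1:5, 1)
      m[r:(r + 2), c:(c + 2)] <- TRUE
      preds[[i]] <- list(mask = m, class = sample(1:2, 1),
                         score = runif(1), frame = "f")
    }
    expect_equal(maskMAP(preds, gts)$mAP, oracleMaskMAP(preds, gts),
                 tolerance = 1e-12)
  }
})

test_that("evaluateScenes paints type maps and scores them", {
  sc <- makeToyScene(type = 3L)
  tb <- buildTargets(sc, sigma = 2.5)
  pb <- bundleFromTargets(sc, tb)
  res <- predictFromBundle(NULL, pb, classify = FALSE)
  res@classProbs <- matrix(c(0, 0, 1, 0, 0, 0, 0), 1, 7)
  res@classLabel <- 3L
  res@detectionScore <- 0.95
  rep <- evaluateScenes(list(res), list(sc))
  expect_equal(typesMIoU(rep), 1)
  expect_equal(maskMAPScore(rep), 1)
  expect_identical(typeLabelMap(sc)[9, 5], 3L)
  expect_identical(typeLabelMap(res)[9, 5], 3L)
})
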
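test_that("extractCentroids keeps thresholded local maxima, capped at four", {
  hm <- matrix(0, 16, 20)
  hm[5, 7] <- 0.9
  pk <- extractCentroids(hm)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk[1, ], c(row = 5, col = 7, score = 0.9))
  expect_identical(nrow(extractCentroids(matrix(0, 16, 20))), 0L)
  # below the peak threshold: dropped
  hm2 <- matrix(0, 16, 20); hm2[3, 3] <- 0.05
  expect_identical(nrow(extractCentroids(hm2)), 0L)
  # six well-separated peaks -> exactly the top four, in score order
  hm3 <- matrix(0, 30, 40)
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  pos <- cbind(c(3, 3, 15, 15, 27, 27), c(5, 25, 5, 25, 5, 25))
  for (i in 1:6) hm3[pos[i, 1], pos[i, 2]] <- sc[i]
  pk3 <- extractCentroids(hm3)
  expect_identical(nrow(pk3), 4L)
  expect_equal(pk3[, "score"], c(0.9, 0.8, 0.7, 0.6))
  # ties broken by (row, col) lexicographic order
  hm4 <- matrix(0, 16, 20)
  hm4[10, 3] <- 0.5; hm4[2, 9] <- 0.5
  pk4 <- extractCentroids(hm4)
  expect_equal(unname(pk4[, "row"]), c(2, 10))
})

test_that("assignInstances matches the exhaustive nearest-centroid oracle", {
  set.seed(30)
  for (i in 1:40) {
    H <- 16L; W <- 20L
    fg <- matrix(runif(H * W) < 0.4, H, W)
    off <- array(rnorm(H * W * 2, 0, 3), c(H, W, 2))
    K <- sample(1:4, 1)
    cents <- cbind(row = runif(K, 1, H), col = runif(K, 1, W),
                   score = sort(runif(K), decreasing = TRUE))
    got <- assignInstances(fg, off, cents)
    expect_identical(got, oracleAssign(fg, off, cents))
  }
})

test_that("assignInstances handles background, ties and empty centroid lists", {
  fg <- matrix(FALSE, 4, 4)
  fg[2, 2] <- TRUE
  off <- array(0, c(4, 4, 2))
  cents <- cbind(row = c(1, 3), col = c(2, 2), score = c(1, 1))
  out <- assignInstances(fg, off, cents)
  expect_identical(out[2, 2], 1L)  # exactly equidistant -> smallest index
  expect_true(all(out[!fg] == 0L))
  expect_warning(res <- assignInstances(fg, off, matrix(numeric(0), 0, 3)),
                 "no centroids")
  expect_true(all(res == 0L))
})

test_that("ground-truth bundles decode back to the ground-truth instances", {
  for (seed in c(2, 9, 21)) {
    sc <- generateScene(synthConfig(), seed = seed)
    tb <- buildTargets(sc, sigma = 2.5)
    if (anyDuplicated(centroidList(tb))) next
    pb <- bundleFromTargets(sc, tb)
    res <- predictFromBundle(NULL, pb, classify = FALSE)
    gt <- instanceMap(sc)
    expect_identical(instanceMap(res) == 0L, gt == 0L)
    ids <- setdiff(sort(unique(as.integer(gt))), 0L)
    seen <- integer(0)
    for (id in ids) {
      lab <- unique(instanceMap(res)[gt == id])
      expect_length(lab, 1L)
      expect_false(lab %in% seen)
      seen <- c(seen, lab)
    }
  }
})

test_that("tiny instances are dropped and ids renumbered compactly", {
  hm <- matrix(0, 16, 20)
  hm[4, 4] <- 0.9; hm[12, 16] <- 0.8
  fg <- matrix(FALSE, 16, 20)
  fg[4, 4] <- TRUE                 # instance 1: a single pixel
  fg[11:13, 15:17] <- TRUE         # instance 2: 9 pixels
  pb <- new("PredictionBundle",
            partLogits = array(rep(ifelse(fg, -5, 5), 5) *
                                 rep(c(1, -1, 1, 1, 1), each = 320),
                               c(16, 20, 5)),
            partProbs = array(0, c(16, 20, 5)),
            offsets = array(0, c(16, 20, 2)),
            heatmap = hm, fSeg = array(1, c(16, 20, 4)))
  # recompute softmax for consistency
  pb@partProbs <- array(apply(pb@partLogits, c(1, 2), function(z)
    exp(z - max(z)) / sum(exp(z - max(z)))), c(5, 16, 20))
  pb@partProbs <- aperm(pb@partProbs, c(2, 3, 1))
  res <- predictFromBundle(NULL, pb,
                           inferenceConfig(minInstancePixels = 4L),
                           classify = FALSE)
  expect_identical(nrow(centroids(res)), 1L)
  expect_identical(sort(unique(as.integer(instanceMap(res)))), c(0L, 1L))
  expect_equal(unname(centroids(res)[1, "score"]), 0.8)
})

test_that("predictFrame returns a structurally valid result on any model", {
  m <- buildModel(modelConfig(preset = "tiny"), seed = 4)
  sc <- generateScene(synthConfig(), seed = 33)
  res <- predictFrame(m, sceneImage(sc))
  n <- nrow(centroids(res))
  expect_lte(n, 4L)
  expect_identical(length(classLabels(res)), n)
  expect_identical(nrow(classProbs(res)), n)
  ids <- setdiff(unique(as.integer(instanceMap(res))), 0L)
  expect_true(all(ids %in% seq_len(n)))
  if (n > 0) {
    expect_equal(rowSums(classProbs(res)), rep(1, n), tolerance = 1e-9)
    expect_true(all(detectionScores(res) >= 0 & detectionScores(res) <= 1))
  }
  # determinism
  res2 <- predictFrame(m, sceneImage(sc))
  expect_identical(instanceMap(res), instanceMap(res2))
  expect_identical(classProbs(res), classProbs(res2))
})
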
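test_that("computeCentroid takes the per-axis median", {
  expect_identical(computeCentroid(rbind(c(0, 0), c(0, 2), c(4, 2))),
                   c(0L, 2L))
  expect_identical(computeCentroid(rbind(c(5, 7))), c(5L, 7L))
  # even-sized sets: mean of the two middle values, then round half away
  # from zero (median of rows {1,2} is 1.5 -> 2)
  expect_identical(computeCentroid(rbind(c(1, 4), c(2, 4))), c(2L, 4L))
  # symmetric disc centred at (10, 10)
  px <- which(outer((1:19 - 10)^2, (1:19 - 10)^2, "+") <= 16,
              arr.ind = TRUE)
  expect_identical(computeCentroid(px), c(10L, 10L))
  expect_error(computeCentroid(matrix(numeric(0), 0, 2)), "empty instance")
})

test_that("makeHeatmap places unit Gaussians combined by maximum", {
  hm <- makeHeatmap(rbind(c(10, 10)), c(21, 21), sigma = 4)
  expect_equal(hm[10, 10], 1)
  expect_equal(hm[14, 10], exp(-1 / 2))  # distance exactly sigma
  # two centroids equidistant from a probe pixel: max, not sum
  hm2 <- makeHeatmap(rbind(c(10, 6), c(10, 14)), c(21, 21), sigma = 4)
  expect_equal(hm2[10, 10], exp(-16 / 32))
  expect_true(all(hm2 <= 1))
  expect_identical(makeHeatmap(matrix(0, 0, 2), c(5, 5), 2),
                   matrix(0, 5, 5))
  expect_error(makeHeatmap(rbind(c(30, 3)), c(21, 21), 4), "out of bounds")
})

test_that("offsets store pixel minus centroid so grouping can undo them", {
  inst <- matrix(0L, 12, 12)
  inst[10, 10] <- 1L
  inst[4, 7] <- 1L
  cl <- rbind("1" = c(4L, 7L))
  off <- makeOffsets(inst, cl)
  expect_equal(off[10, 10, ], c(6, 3))  # p - centroid
  expect_equal(off[4, 7, ], c(0, 0))    # p equals its centroid
  expect_equal(off[1, 1, ], c(0, 0))    # background
  expect_error(makeOffsets(inst, rbind("9" = c(1L, 1L))), "no centroid")
})

test_that("buildTargets satisfies the bundle invariants", {
  for (seed in c(3, 14, 26)) {
    sc <- generateScene(synthConfig(), seed = seed)
    tb <- buildTargets(sc, sigma = 2.5)
    expect_identical(partTarget(tb), partMap(sc))
    expect_identical(foregroundMask(tb), partMap(sc) != 0L)
    hm <- heatmapTarget(tb)
    expect_true(all(hm >= 0 & hm <= 1))
    cl <- centroidList(tb)
    if (nrow(cl) > 0) {
      expect_equal(max(hm), 1)
      for (k in seq_len(nrow(cl))) expect_equal(hm[cl[k, 1], cl[k, 2]], 1)
      # p - offset(p) must recover the integer centroid exactly
      off <- offsetTarget(tb)
      inst <- instanceMap(sc)
      for (k in seq_len(nrow(cl))) {
        id <- as.integer(rownames(cl)[k])
        px <- which(inst == id, arr.ind = TRUE)
        expect_true(all(px[, 1] - off[, , 1][inst == id] == cl[k, 1]))
        expect_true(all(px[, 2] - off[, , 2][inst == id] == cl[k, 2]))
      }
    } else {
      expect_true(all(hm == 0))
    }
    expect_true(all(offsetTarget(tb)[!foregroundMask(tb)] == 0))
  }
})

test_that("an empty scene yields all-zero targets", {
  cfg <- synthConfig(nInstruments = c(0L, 0L))
  sc <- generateScene(cfg, seed = 5)
  tb <- buildTargets(sc, sigma = 2.5)
  expect_true(all(heatmapTarget(tb) == 0))
  expect_true(all(offsetTarget(tb) == 0))
  expect_true(all(partTarget(tb) == 0L))
  expect_identical(nrow(centroidList(tb)), 0L)
})

test_that("a multi-instrument scene has one unit peak per instance", {
  # find a scene with 3 instruments and distinct rounded centroids
  found <- FALSE
  for (seed in 1:60) {
    sc <- generateScene(synthConfig(nInstruments = c(3L, 3L)), seed = seed)
    tb <- buildTargets(sc, sigma = 2.5)
    cl <- centroidList(tb)
    if (nrow(cl) == 3L && !anyDuplicated(cl)) {
      found <- TRUE
      # brute-force count of exact-1 pixels
      expect_identical(sum(heatmapTarget(tb) == 1), 3L)
      break
    }
  }
  expect_true(found)
})

test_that("the heatmap is invariant to instance id permutation", {
  sc <- generateScene(synthConfig(nInstruments = c(2L, 2L)), seed = 8)
  inst <- instanceMap(sc)
  expect_identical(sort(unique(as.integer(inst))), c(0L, 1L, 2L))
  perm <- inst
  perm[inst == 1L] <- 2L
  perm[inst == 2L] <- 1L
  sc2 <- LabeledScene(sceneImage(sc), perm, partMap(sc),
                      types = setNames(instrumentTypes(sc)[c("2", "1")],
                                       c("1", "2")),
                      clasperVisible = clasperVisible(sc)[c("2", "1")],
                      frameId = "perm")
  names(sc2@clasperVisible) <- c("1", "2")
  expect_equal(heatmapTarget(buildTargets(sc2, 2.5)),
               heatmapTarget(buildTargets(sc, 2.5)))
})
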
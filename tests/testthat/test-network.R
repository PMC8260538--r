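test_that("the tiny model honours the output shape contract", {
  m <- buildModel(modelConfig(preset = "tiny"), seed = 1)
  img <- array(runif(64 * 80 * 3), c(64, 80, 3))
  pb <- forwardModel(m, img)
  expect_identical(dim(partLogits(pb)), c(64L, 80L, 5L))
  expect_identical(dim(offsetField(pb)), c(64L, 80L, 2L))
  expect_identical(dim(heatmap(pb)), c(64L, 80L))
  expect_true(all(heatmap(pb) > 0 & heatmap(pb) < 1))
  sums <- apply(partProbs(pb), c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
})

test_that("the full preset keeps 32 f_seg channels and is the larger model", {
  mFull <- buildModel(modelConfig(preset = "full"), seed = 1)
  mTiny <- buildModel(modelConfig(preset = "tiny"), seed = 1)
  expect_identical(mFull$config$fSegChannels, 32L)
  expect_gt(modelParameterCount(mFull), modelParameterCount(mTiny))
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))  # divisible by stride 32
  pb <- forwardModel(mFull, img)
  expect_identical(dim(fSeg(pb))[3], 32L)
  expect_identical(dim(heatmap(pb)), c(64L, 96L))
})

test_that("inputs not divisible by the encoder stride are rejected", {
  m <- buildModel(modelConfig(preset = "tiny"), seed = 1)
  expect_error(forwardModel(m, array(0.5, c(64, 50, 3))), "not divisible")
})

test_that("evaluation-mode forwards are deterministic", {
  m <- buildModel(modelConfig(preset = "tiny"), seed = 3)
  img <- array(runif(64 * 80 * 3), c(64, 80, 3))
  p1 <- forwardModel(m, img)
  p2 <- forwardModel(m, img)
  expect_identical(heatmap(p1), heatmap(p2))
  expect_identical(fSeg(p1), fSeg(p2))
})

test_that("classifyInstance ignores masked-out pixels and returns a distribution", {
  m <- buildModel(modelConfig(preset = "tiny"), seed = 2)
  set.seed(20)
  fs <- array(rnorm(64 * 80 * 8), c(64, 80, 8))
  mask <- matrix(FALSE, 64, 80)
  mask[20:40, 30:50] <- TRUE
  p <- classifyInstance(m, fs, mask)
  expect_length(p, 7L)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # perturb only masked-out pixels: bitwise identical output
  fs2 <- fs
  for (ch in 1:8) {
    pl <- fs2[, , ch]
    pl[!mask] <- rnorm(sum(!mask), 0, 50)
    fs2[, , ch] <- pl
  }
  expect_identical(classifyInstance(m, fs2, mask), p)
  expect_error(classifyInstance(m, fs, matrix(FALSE, 64, 80)),
               "empty instance")
})

test_that("global max pooling makes the classifier translation tolerant", {
  m <- buildModel(modelConfig(preset = "tiny"), seed = 2)
  fs <- array(0, c(64, 80, 8))
  patch <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  place <- function(r0, c0) {
    f <- fs
    f[r0:(r0 + 7), c0:(c0 + 7), ] <- patch
    mk <- matrix(FALSE, 64, 80)
    mk[r0:(r0 + 7), c0:(c0 + 7)] <- TRUE
    classifyInstance(m, f, mk)
  }
  # translation by the total pooling stride (16 px), away from borders;
  # exact up to the zero-padding border effects of the deepest conv grid
  a <- place(17, 17)
  b <- place(33, 49)
  expect_identical(which.max(a), which.max(b))
  expect_equal(a, b, tolerance = 0.05)
  # an unrelated mask position must NOT produce the same distribution
  expect_gt(max(abs(place(17, 17) - place(20, 24))), 1e-6)
})

test_that("the presence prior feeds a second fully connected layer", {
  mc <- modelConfig(preset = "tiny", usePrior = TRUE)
  m <- buildModel(mc, seed = 5)
  expect_true("cls.fc2.W" %in% names(m$params))
  fs <- array(rnorm(64 * 80 * 8), c(64, 80, 8))
  mask <- matrix(FALSE, 64, 80); mask[10:20, 10:20] <- TRUE
  pAll <- classifyInstance(m, fs, mask, prior = rep(1, 7))
  expect_equal(sum(pAll), 1, tolerance = 1e-9)
  pSome <- classifyInstance(m, fs, mask, prior = c(1, 0, 0, 1, 0, 0, 0))
  expect_false(identical(pAll, pSome))
  expect_error(classifyInstance(m, fs, mask), "supply a length")
  mNo <- buildModel(modelConfig(preset = "tiny"), seed = 5)
  expect_error(classifyInstance(mNo, fs, mask, prior = rep(1, 7)),
               "not built with usePrior")
})

test_that("variants change exactly the advertised heads", {
  base <- buildModel(modelConfig(preset = "tiny"), seed = 9)
  bin <- buildModel(modelConfig(preset = "tiny", variant = "binary_seg"),
                    seed = 9)
  expect_identical(ncol(bin$params[["head.part.W"]]), 2L)
  # offset/heatmap heads unchanged in shape
  for (nm in c("head.off.W", "head.hm.W")) {
    expect_identical(dim(base$params[[nm]]), dim(bin$params[[nm]]))
  }
  for (nm in grep("^dec.off", names(base$params), value = TRUE)) {
    expect_identical(dim(base$params[[nm]]), dim(bin$params[[nm]]))
  }
  sd <- buildModel(modelConfig(preset = "tiny",
                               variant = "single_decoder"), seed = 9)
  expect_false(any(grepl("^dec.seg", names(sd$params))))
  img <- array(runif(64 * 80 * 3), c(64, 80, 3))
  expect_identical(dim(fSeg(forwardModel(sd, img)))[3],
                   2L * sd$config$fSegChannels)  # doubled channels
  st <- buildModel(modelConfig(preset = "tiny",
                               variant = "semantic_type"), seed = 9)
  expect_false(any(grepl("^cls\\.", names(st$params))))
  tm <- semanticTypeMap(st, img)
  expect_true(all(tm %in% 0:7))
  expect_error(classifyInstance(st, array(0, c(64, 80, 8)),
                                matrix(TRUE, 64, 80)), "no instance")
})
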
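# The analytic gradients behind the training loop, checked against
# central finite differences and (for the convolution) a naive per-pixel
# reference implementation.

ops <- asNamespace("CentroidSeg")

numGrad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + h
    x2 <- x; x2[i] <- x2[i] - h
    g[i] <- (f(x1) - f(x2)) / (2 * h)
  }
  g
}

naiveConv <- function(X, B, H, W, Wm, bias) {
  C <- ncol(X)
  Co <- ncol(Wm)
  Y <- matrix(rep(bias, each = nrow(X)), nrow(X), Co)
  for (b in seq_len(B)) for (r in seq_len(H)) for (c in seq_len(W)) {
    out <- (b - 1) * H * W + (c - 1) * H + r
    k <- 0
    for (dc in -1:1) for (dr in -1:1) {
      k <- k + 1
      ri <- r + dr; ci <- c + dc
      if (ri < 1 || ri > H || ci < 1 || ci > W) next
      inp <- (b - 1) * H * W + (ci - 1) * H + ri
      Y[out, ] <- Y[out, ] +
        X[inp, ] %*% Wm[((k - 1) * C + 1):(k * C), , drop = FALSE]
    }
  }
  Y
}

test_that("the compiled convolution matches a naive per-pixel reference", {
  set.seed(10)
  for (i in 1:4) {
    B <- sample(1:3, 1); H <- sample(3:7, 1); W <- sample(3:9, 1)
    C <- sample(1:5, 1); Co <- sample(1:4, 1)
    X <- matrix(rnorm(B * H * W * C), B * H * W, C)
    Wm <- matrix(rnorm(9 * C * Co), 9 * C, Co)
    b <- rnorm(Co)
    expect_equal(ops$convForward(X, B, H, W, Wm, b)$out,
                 naiveConv(X, B, H, W, Wm, b), tolerance = 1e-12)
  }
})

test_that("convolution gradients agree with finite differences", {
  set.seed(11)
  B <- 2L; H <- 5L; W <- 4L; C <- 3L; Co <- 2L
  X <- matrix(rnorm(B * H * W * C), B * H * W, C)
  Wm <- matrix(rnorm(9 * C * Co) * 0.3, 9 * C, Co)
  b <- rnorm(Co)
  dY <- matrix(rnorm(B * H * W * Co), B * H * W, Co)
  fw <- ops$convForward(X, B, H, W, Wm, b)
  g <- ops$convBackward(dY, fw, B, H, W, Wm)
  expect_equal(g$dX, matrix(numGrad(function(Xm)
    sum(ops$convForward(matrix(Xm, nrow(X)), B, H, W, Wm, b)$out * dY),
    X), nrow(X)), tolerance = 1e-6)
  expect_equal(g$dW, matrix(numGrad(function(Wv)
    sum(ops$convForward(X, B, H, W, matrix(Wv, nrow(Wm)), b)$out * dY),
    Wm), nrow(Wm)), tolerance = 1e-6)
  expect_equal(g$db, numGrad(function(bv)
    sum(ops$convForward(X, B, H, W, Wm, bv)$out * dY), b),
    tolerance = 1e-6)
})

test_that("group norm is per-image and its gradients check out", {
  set.seed(12)
  B <- 2L; H <- 4L; W <- 3L; C <- 4L
  X <- matrix(rnorm(B * H * W * C), B * H * W, C)
  ga <- rnorm(C); be <- rnorm(C)
  fw <- ops$groupNormForward(X, B, ga, be, 2L)
  # image 1 alone gives identical output: no batch statistics
  fw1 <- ops$groupNormForward(X[1:(H * W), , drop = FALSE], 1L, ga, be, 2L)
  expect_equal(fw$out[1:(H * W), ], fw1$out, tolerance = 1e-12)
  dY <- matrix(rnorm(B * H * W * C), B * H * W, C)
  g <- ops$groupNormBackward(dY, fw, ga)
  expect_equal(g$dX, matrix(numGrad(function(Xv)
    sum(ops$groupNormForward(matrix(Xv, nrow(X)), B, ga, be, 2L)$out * dY),
    X), nrow(X)), tolerance = 1e-5)
  expect_equal(g$dgamma, numGrad(function(gv)
    sum(ops$groupNormForward(X, B, gv, be, 2L)$out * dY), ga),
    tolerance = 1e-6)
  expect_equal(g$dbeta, numGrad(function(bv)
    sum(ops$groupNormForward(X, B, ga, bv, 2L)$out * dY), be),
    tolerance = 1e-6)
})

test_that("max pooling and upsampling gradients check out", {
  set.seed(13)
  B <- 2L; H <- 6L; W <- 4L; C <- 3L
  X <- matrix(rnorm(B * H * W * C), B * H * W, C)
  fw <- ops$maxPoolForward(X, B, H, W)
  dY <- matrix(rnorm(nrow(fw$out) * C), nrow(fw$out), C)
  g <- ops$maxPoolBackward(dY, fw, B, H, W, C)
  expect_equal(g, matrix(numGrad(function(Xv)
    sum(ops$maxPoolForward(matrix(Xv, nrow(X)), B, H, W)$out * dY),
    X, h = 1e-7), nrow(X)), tolerance = 1e-5)
  fu <- ops$upsampleForward(X, B, H, W)
  expect_identical(nrow(fu$out), 4L * nrow(X))
  dU <- matrix(rnorm(nrow(fu$out) * C), nrow(fu$out), C)
  gu <- ops$upsampleBackward(dU, B, H, W)
  expect_equal(gu, matrix(numGrad(function(Xv)
    sum(ops$upsampleForward(matrix(Xv, nrow(X)), B, H, W)$out * dU),
    X), nrow(X)), tolerance = 1e-6)
})

test_that("AdamW decays only weight matrices", {
  p <- list("a.W" = matrix(1, 2, 2), "a.b" = c(1, 1))
  st <- ops$adamwInit(p)
  g <- list("a.W" = matrix(0, 2, 2), "a.b" = c(0, 0))
  up <- ops$adamwStep(p, g, st, lr = 0.1, decay = 0.5)
  expect_lt(up$params[["a.W"]][1, 1], 1)   # decayed
  expect_equal(up$params[["a.b"]], c(1, 1))  # untouched
})
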
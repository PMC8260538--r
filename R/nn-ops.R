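# Low-level neural-network primitives.
#
# A batched feature map is a dense numeric matrix with B*H*W rows (image
# blocks contiguous, pixels within an image in the column-major order of an
# H x W matrix) and one column per channel. All convolutions are 3x3 with
# zero padding 1, so spatial shape is preserved; downsampling is explicit
# 2x2 max pooling and upsampling is nearest-neighbour x2. Gradients are
# hand-derived; convolutions run through the compiled im2col kernels in
# src/conv_ops.cpp (GEMM via the system BLAS), everything else is
# vectorised R with per-shape memoised index tables.

.idx_cache <- new.env(parent = emptyenv())

.stack_idx <- function(idx, block, B) {
  # replicate a per-image index over B contiguous blocks of size `block`
  if (B == 1L) return(idx)
  n <- length(idx)
  rep.int(idx, B) + rep(block * (seq_len(B) - 1L), each = n)
}

.pool_idx <- function(B, H, W) {
  # floor division: an odd trailing row/column is dropped (zero gradient)
  key <- sprintf("pool%dx%dx%d", B, H, W)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  r <- rep.int(seq_len(Ho), times = Wo)
  cc <- rep(seq_len(Wo), each = Ho)
  sub <- function(dr, dc) .stack_idx((2L * cc - 2L + dc) * H + (2L * r - 1L + dr),
                                     H * W, B)
  out <- list(i = list(sub(0L, 0L), sub(1L, 0L), sub(0L, 1L), sub(1L, 1L)),
              Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

.up_idx <- function(B, H, W) {
  # input H x W -> output 2H x 2W, nearest neighbour
  key <- sprintf("up%dx%dx%d", B, H, W)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Ho <- 2L * H
  Wo <- 2L * W
  r <- rep.int(seq_len(Ho), times = Wo)
  cc <- rep(seq_len(Wo), each = Ho)
  src <- .stack_idx((((cc + 1L) %/% 2L) - 1L) * H + ((r + 1L) %/% 2L), H * W, B)
  phase <- vector("list", 4L)
  ri <- rep.int(seq_len(H), times = W)
  ci <- rep(seq_len(W), each = H)
  k <- 0L
  for (pc in 0:1) for (pr in 0:1) {
    k <- k + 1L
    phase[[k]] <- .stack_idx((2L * ci - 2L + pc) * Ho + (2L * ri - 1L + pr),
                             Ho * Wo, B)
  }
  out <- list(src = src, phase = phase, Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

convForward <- function(X, B, H, W, weight, bias) {
  list(out = .csConvFwd(X, B, H, W, weight, bias), X = X)
}

convBackward <- function(dY, cache, B, H, W, weight, needX = TRUE) {
  g <- .csConvBwd(cache$X, dY, B, H, W, weight, needX)
  g$db <- as.numeric(g$db)
  g
}

.gn_groups <- function(C, groups) {
  g <- min(groups, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

# Group normalisation over (pixels x group-channels) per image; batch
# statistics are never mixed, so behaviour is identical at any batch size.
groupNormForward <- function(X, B, gamma, beta, groups, eps = 1e-5) {
  g <- .gn_groups(ncol(X), groups)
  fw <- .csGroupNormFwd(X, B, g, eps)
  Y <- fw$Xh * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(out = Y, Xh = fw$Xh, istd = fw$istd, g = g)
}

groupNormBackward <- function(dY, cache, gamma) {
  dXh <- dY * rep(gamma, each = nrow(dY))
  dgamma <- colSums(dY * cache$Xh)
  dbeta <- colSums(dY)
  dX <- .csGroupNormBwd(dXh, cache$Xh, cache$istd, nrow(cache$istd),
                        cache$g)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

reluBackward <- function(dY, cache) dY * cache$mask

maxPoolForward <- function(X, B, H, W) {
  pi <- .pool_idx(B, H, W)
  Y <- X[pi$i[[1L]], , drop = FALSE]
  win <- matrix(1L, nrow(Y), ncol(Y))
  for (k in 2:4) {
    cand <- X[pi$i[[k]], , drop = FALSE]
    better <- cand > Y
    better[is.na(better)] <- FALSE  # NaN inputs propagate via slot 1
    Y[better] <- cand[better]
    win[better] <- k
  }
  list(out = Y, win = win, Ho = pi$Ho, Wo = pi$Wo)
}

maxPoolBackward <- function(dY, cache, B, H, W, C) {
  pi <- .pool_idx(B, H, W)
  dX <- matrix(0, B * H * W, C)
  for (k in 1:4) {
    m <- dY * (cache$win == k)
    dX[pi$i[[k]], ] <- dX[pi$i[[k]], , drop = FALSE] + m
  }
  dX
}

upsampleForward <- function(X, B, H, W) {
  ui <- .up_idx(B, H, W)
  list(out = X[ui$src, , drop = FALSE], Ho = ui$Ho, Wo = ui$Wo)
}

upsampleBackward <- function(dY, B, H, W) {
  ui <- .up_idx(B, H, W)
  dX <- dY[ui$phase[[1L]], , drop = FALSE]
  for (k in 2:4) dX <- dX + dY[ui$phase[[k]], , drop = FALSE]
  dX
}

softmaxRows <- function(X) {
  m <- X[, 1L]
  for (j in seq_len(ncol(X))[-1L]) m <- pmax(m, X[, j])
  E <- exp(X - m)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# AdamW over a flat named list of parameter arrays. Decoupled weight decay
# is applied to convolution / fully-connected weights only (names ending in
# ".W"), never to normalisation parameters or biases.
adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamwStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, decay = 1e-4) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (grepl("\\.W$", nm)) step <- step + lr * decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
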
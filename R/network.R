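# Architecture: a shared encoder feeding two lightweight decoder heads
# (part segmentation; offsets + centroid heatmap) with long skip
# connections from the last three encoder stages, group normalisation
# everywhere, and a shallow per-instance classifier on the masked
# segmentation features. Two presets: "full" mirrors EfficientNet-B0
# stage widths (stride 32); "tiny" is a CPU-scale 3-stage encoder
# (stride 8). Everything runs on the batched matrix representation of
# nn-ops.R; forward passes cache what the analytic backward passes in
# pipeline.R need.

#' Model configuration
#'
#' @param preset "tiny" (3-stage encoder, stride 8, CPU-scale) or "full"
#'   (5-stage encoder mirroring EfficientNet-B0 stage widths, stride 32).
#' @param nParts number of instrument part labels (default 4).
#' @param nClasses number of instrument types (default 7).
#' @param fSegChannels channels of the final segmentation feature map
#'   consumed by the classifier (default 32 for "full", 8 for "tiny").
#' @param variant "proposed", "single_decoder" (one decoder with doubled
#'   channels feeding both heads), "binary_seg" (2-class part head), or
#'   "semantic_type" (third decoder predicts per-pixel type logits and
#'   replaces the instance classifier).
#' @param usePrior concatenate a binary type-presence vector to the
#'   pooled classifier feature (adds a second fully connected layer).
#' @param normGroups group-normalisation groups (default 8).
#' @param dropoutFseg channel-dropout rate applied to the classifier
#'   input during training (default 0.2).
#' @param classifierHidden width of the hidden FC layer used when
#'   \code{usePrior} (default 64 full / 32 tiny).
#' @param widths encoder stage widths (defaults per preset).
#' @param classifierWidths widths of the four classifier conv layers.
#' @param offsetScale fixed scale applied to the raw offset-head output so
#'   that offsets in pixels are reachable early in training; default
#'   diag/8 of the input, resolved at build time from the first forward.
#' @return A validated configuration list.
#' @export
modelConfig <- function(preset = c("tiny", "full"), nParts = 4L,
                        nClasses = 7L, fSegChannels = NULL,
                        variant = c("proposed", "single_decoder",
                                    "binary_seg", "semantic_type"),
                        usePrior = FALSE, normGroups = 8L,
                        dropoutFseg = 0.2, classifierHidden = NULL,
                        widths = NULL, classifierWidths = NULL,
                        offsetScale = NULL) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  if (is.null(widths))
    widths <- if (preset == "tiny") c(8L, 16L, 32L)
              else c(16L, 24L, 40L, 112L, 320L)
  if (is.null(fSegChannels))
    fSegChannels <- if (preset == "tiny") 12L else 32L
  if (is.null(classifierHidden))
    classifierHidden <- if (preset == "tiny") 32L else 64L
  if (is.null(classifierWidths))
    classifierWidths <- if (preset == "tiny") c(12L, 24L, 24L, 24L)
                        else c(32L, 64L, 64L, 64L)
  stopifnot(fSegChannels >= 1L, length(widths) >= 3L,
            length(classifierWidths) == 4L, normGroups >= 1L,
            dropoutFseg >= 0, dropoutFseg < 1)
  list(preset = preset, nParts = as.integer(nParts),
       nClasses = as.integer(nClasses),
       fSegChannels = as.integer(fSegChannels), variant = variant,
       usePrior = usePrior, normGroups = as.integer(normGroups),
       dropoutFseg = dropoutFseg,
       classifierHidden = as.integer(classifierHidden),
       widths = as.integer(widths),
       classifierWidths = as.integer(classifierWidths),
       offsetScale = offsetScale,
       stride = 2L^length(widths))
}

.heNormal <- function(nin, nout, fan) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)
}

.addConv <- function(params, name, cin, cout) {
  params[[paste0(name, ".W")]] <- .heNormal(9L * cin, cout, 9L * cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

.addGN <- function(params, name, c) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- numeric(c)
  params
}

.addCGR <- function(params, prefix, cin, cout) {
  params <- .addConv(params, paste0(prefix, ".c"), cin, cout)
  .addGN(params, paste0(prefix, ".g"), cout)
}

.add1x1 <- function(params, name, cin, cout) {
  params[[paste0(name, ".W")]] <- .heNormal(cin, cout, cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

.decoderWidths <- function(cfg) {
  S <- length(cfg$widths)
  w <- rev(cfg$widths)
  mult <- if (cfg$variant == "single_decoder") 2L else 1L
  list(blocks = w * mult, fSeg = cfg$fSegChannels * mult, S = S,
       mult = mult)
}

.addDecoder <- function(params, name, cfg, bottomWidth) {
  dw <- .decoderWidths(cfg)
  S <- dw$S
  cur <- bottomWidth
  for (j in seq_len(S)) {
    skipW <- if (j <= 3L) cfg$widths[S - j + 1L] else 0L
    cin <- cur + skipW
    params <- .addCGR(params, sprintf("%s.b%d.1", name, j), cin,
                      dw$blocks[j])
    params <- .addCGR(params, sprintf("%s.b%d.2", name, j), dw$blocks[j],
                      dw$blocks[j])
    cur <- dw$blocks[j]
  }
  for (k in 1:3) {
    cin <- if (k == 1L) cur else dw$fSeg
    params <- .addCGR(params, sprintf("%s.fin.%d", name, k), cin, dw$fSeg)
  }
  params
}

#' Build a model
#'
#' Allocates and initialises all parameters (He initialisation for
#' convolutions, unit gain / zero shift for group norm). The heatmap head
#' bias starts at logit(0.01) so the focal loss sees a near-empty heatmap
#' initially. The returned model is a plain list with \code{$params} (flat
#' named list) and \code{$config}; it is mutated functionally by training.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed integer seed for the parameter initialisation.
#' @return A model list with elements \code{params} and \code{config}.
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  .withSeed(seed, .buildModelImpl(config))
}

.buildModelImpl <- function(cfg) {
  p <- list()
  w <- cfg$widths
  S <- length(w)
  cin <- 3L
  for (s in seq_len(S)) {
    p <- .addCGR(p, sprintf("enc.s%d.1", s), cin, w[s])
    p <- .addCGR(p, sprintf("enc.s%d.2", s), w[s], w[s])
    cin <- w[s]
  }
  dw <- .decoderWidths(cfg)
  nPartOut <- if (cfg$variant == "binary_seg") 2L else cfg$nParts + 1L
  if (cfg$variant == "single_decoder") {
    p <- .addDecoder(p, "dec.shared", cfg, w[S])
    p <- .add1x1(p, "head.part", dw$fSeg, nPartOut)
    p <- .add1x1(p, "head.off", dw$fSeg, 2L)
    p <- .add1x1(p, "head.hm", dw$fSeg, 1L)
  } else {
    p <- .addDecoder(p, "dec.seg", cfg, w[S])
    p <- .addDecoder(p, "dec.off", cfg, w[S])
    p <- .add1x1(p, "head.part", dw$fSeg, nPartOut)
    p <- .add1x1(p, "head.off", dw$fSeg, 2L)
    p <- .add1x1(p, "head.hm", dw$fSeg, 1L)
  }
  p[["head.hm.b"]][] <- log(0.01 / 0.99)
  if (cfg$variant == "semantic_type") {
    p <- .addDecoder(p, "dec.type", cfg, w[S])
    p <- .add1x1(p, "head.type", dw$fSeg, cfg$nClasses + 1L)
  } else {
    cw <- cfg$classifierWidths
    cin <- dw$fSeg
    for (k in 1:4) {
      p <- .addCGR(p, sprintf("cls.c%d", k), cin, cw[k])
      cin <- cw[k]
    }
    if (cfg$usePrior) {
      p[["cls.fc1.W"]] <- .heNormal(cin + cfg$nClasses, cfg$classifierHidden,
                                    cin + cfg$nClasses)
      p[["cls.fc1.b"]] <- numeric(cfg$classifierHidden)
      p[["cls.fc2.W"]] <- .heNormal(cfg$classifierHidden, cfg$nClasses,
                                    cfg$classifierHidden)
      p[["cls.fc2.b"]] <- numeric(cfg$nClasses)
    } else {
      p[["cls.fc1.W"]] <- .heNormal(cin, cfg$nClasses, cin)
      p[["cls.fc1.b"]] <- numeric(cfg$nClasses)
    }
  }
  list(params = p, config = cfg)
}

#' Number of parameters of a model
#'
#' @param model a model from \code{\link{buildModel}}.
#' @return Integer parameter count.
#' @export
modelParameterCount <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

# ---- forward primitives (with caches for the analytic backward) --------

.fwdCGR <- function(p, prefix, X, B, H, W, groups) {
  cv <- convForward(X, B, H, W, p[[paste0(prefix, ".c.W")]],
                    p[[paste0(prefix, ".c.b")]])
  gn <- groupNormForward(cv$out, B, p[[paste0(prefix, ".g.gamma")]],
                         p[[paste0(prefix, ".g.beta")]], groups)
  rl <- reluForward(gn$out)
  list(out = rl$out, conv = cv, gn = gn, relu = rl)
}

.bwdCGR <- function(p, prefix, dY, cache, B, H, W, gacc, needX = TRUE) {
  dY <- reluBackward(dY, cache$relu)
  gb <- groupNormBackward(dY, cache$gn, p[[paste0(prefix, ".g.gamma")]])
  .accGrad(gacc, paste0(prefix, ".g.gamma"), gb$dgamma)
  .accGrad(gacc, paste0(prefix, ".g.beta"), gb$dbeta)
  cb <- convBackward(gb$dX, cache$conv, B, H, W,
                     p[[paste0(prefix, ".c.W")]], needX = needX)
  .accGrad(gacc, paste0(prefix, ".c.W"), cb$dW)
  .accGrad(gacc, paste0(prefix, ".c.b"), cb$db)
  cb$dX
}

.accGrad <- function(gacc, name, value) {
  cur <- gacc[[name]]
  if (is.null(cur)) gacc[[name]] <- value
  else gacc[[name]] <- cur + value
}

.fwdEncoder <- function(model, X, B, H, W) {
  cfg <- model$config
  p <- model$params
  S <- length(cfg$widths)
  skips <- vector("list", S)
  caches <- vector("list", S)
  h <- H; w <- W
  cur <- X
  for (s in seq_len(S)) {
    c1 <- .fwdCGR(p, sprintf("enc.s%d.1", s), cur, B, h, w, cfg$normGroups)
    c2 <- .fwdCGR(p, sprintf("enc.s%d.2", s), c1$out, B, h, w,
                  cfg$normGroups)
    pl <- maxPoolForward(c2$out, B, h, w)
    skips[[s]] <- list(out = c2$out, H = h, W = w)
    caches[[s]] <- list(c1 = c1, c2 = c2, pool = pl, H = h, W = w)
    cur <- pl$out
    h <- h %/% 2L; w <- w %/% 2L
  }
  list(bottom = cur, H = h, W = w, skips = skips, caches = caches)
}

.bwdEncoder <- function(model, enc, dBottom, dSkips, B, gacc) {
  cfg <- model$config
  p <- model$params
  S <- length(cfg$widths)
  cur <- dBottom
  for (s in rev(seq_len(S))) {
    ca <- enc$caches[[s]]
    d2 <- maxPoolBackward(cur, ca$pool, B, ca$H, ca$W,
                          ncol(ca$c2$out))
    if (!is.null(dSkips[[s]])) d2 <- d2 + dSkips[[s]]
    d1 <- .bwdCGR(p, sprintf("enc.s%d.2", s), d2, ca$c2, B, ca$H, ca$W,
                  gacc)
    cur <- .bwdCGR(p, sprintf("enc.s%d.1", s), d1, ca$c1, B, ca$H, ca$W,
                   gacc, needX = s > 1L)
  }
  cur
}

.fwdDecoder <- function(model, name, enc, B) {
  cfg <- model$config
  p <- model$params
  dw <- .decoderWidths(cfg)
  S <- dw$S
  cur <- enc$bottom
  h <- enc$H; w <- enc$W
  blocks <- vector("list", S)
  for (j in seq_len(S)) {
    up <- upsampleForward(cur, B, h, w)
    h <- 2L * h; w <- 2L * w
    x <- up$out
    skipC <- 0L
    if (j <= 3L) {
      sk <- enc$skips[[S - j + 1L]]
      skipC <- ncol(sk$out)
      x <- cbind(x, sk$out)
    }
    c1 <- .fwdCGR(p, sprintf("%s.b%d.1", name, j), x, B, h, w,
                  cfg$normGroups)
    c2 <- .fwdCGR(p, sprintf("%s.b%d.2", name, j), c1$out, B, h, w,
                  cfg$normGroups)
    blocks[[j]] <- list(c1 = c1, c2 = c2, H = h, W = w, skipC = skipC,
                        upC = ncol(up$out))
    cur <- c2$out
  }
  fin <- vector("list", 3L)
  for (k in 1:3) {
    fin[[k]] <- .fwdCGR(p, sprintf("%s.fin.%d", name, k), cur, B, h, w,
                        cfg$normGroups)
    cur <- fin[[k]]$out
  }
  list(out = cur, blocks = blocks, fin = fin, H = h, W = w)
}

.bwdDecoder <- function(model, name, dec, enc, dOut, B, gacc) {
  cfg <- model$config
  p <- model$params
  S <- length(cfg$widths)
  cur <- dOut
  h <- dec$H; w <- dec$W
  for (k in 3:1) {
    cur <- .bwdCGR(p, sprintf("%s.fin.%d", name, k), cur, dec$fin[[k]], B,
                   h, w, gacc)
  }
  dSkips <- vector("list", S)
  for (j in rev(seq_len(S))) {
    bl <- dec$blocks[[j]]
    d1 <- .bwdCGR(p, sprintf("%s.b%d.2", name, j), cur, bl$c2, B, bl$H,
                  bl$W, gacc)
    dx <- .bwdCGR(p, sprintf("%s.b%d.1", name, j), d1, bl$c1, B, bl$H,
                  bl$W, gacc)
    dUp <- dx[, seq_len(bl$upC), drop = FALSE]
    if (bl$skipC > 0L) {
      s <- S - j + 1L
      dSk <- dx[, bl$upC + seq_len(bl$skipC), drop = FALSE]
      if (is.null(dSkips[[s]])) dSkips[[s]] <- dSk
      else dSkips[[s]] <- dSkips[[s]] + dSk
    }
    cur <- upsampleBackward(dUp, B, bl$H %/% 2L, bl$W %/% 2L)
    h <- bl$H %/% 2L; w <- bl$W %/% 2L
  }
  list(dBottom = cur, dSkips = dSkips)
}

.fwd1x1 <- function(p, name, X) {
  X %*% p[[paste0(name, ".W")]] + rep(p[[paste0(name, ".b")]],
                                      each = nrow(X))
}

.bwd1x1 <- function(p, name, X, dY, gacc) {
  .accGrad(gacc, paste0(name, ".W"), crossprod(X, dY))
  .accGrad(gacc, paste0(name, ".b"), colSums(dY))
  tcrossprod(dY, p[[paste0(name, ".W")]])
}

.resolveOffsetScale <- function(cfg, H, W) {
  if (!is.null(cfg$offsetScale)) cfg$offsetScale else sqrt(H^2 + W^2) / 8
}

# full batched forward; returns raw matrices plus every cache needed by
# the training backward pass in pipeline.R
.forwardBatch <- function(model, X, B, H, W) {
  cfg <- model$config
  if (H %% cfg$stride != 0L || W %% cfg$stride != 0L)
    stop(sprintf("input %dx%d not divisible by the encoder stride %d",
                 H, W, cfg$stride))
  p <- model$params
  enc <- .fwdEncoder(model, X, B, H, W)
  if (cfg$variant == "single_decoder") {
    dec <- .fwdDecoder(model, "dec.shared", enc, B)
    fseg <- dec$out
    offFeat <- dec$out
    decs <- list(shared = dec)
  } else {
    dseg <- .fwdDecoder(model, "dec.seg", enc, B)
    doff <- .fwdDecoder(model, "dec.off", enc, B)
    fseg <- dseg$out
    offFeat <- doff$out
    decs <- list(seg = dseg, off = doff)
  }
  partLogits <- .fwd1x1(p, "head.part", fseg)
  offScale <- .resolveOffsetScale(cfg, H, W)
  offRaw <- .fwd1x1(p, "head.off", offFeat)
  hmLogit <- .fwd1x1(p, "head.hm", offFeat)
  out <- list(enc = enc, decs = decs, fseg = fseg, offFeat = offFeat,
              partLogits = partLogits, partProbs = softmaxRows(partLogits),
              offsets = offRaw * offScale, offRaw = offRaw,
              hmLogit = hmLogit, heatmap = sigmoid(as.numeric(hmLogit)),
              offScale = offScale, B = B, H = H, W = W)
  if (cfg$variant == "semantic_type") {
    dtype <- .fwdDecoder(model, "dec.type", enc, B)
    out$decs$type <- dtype
    out$typeLogits <- .fwd1x1(p, "head.type", dtype$out)
    out$typeProbs <- softmaxRows(out$typeLogits)
  }
  out
}

#' Run the network on one image
#'
#' Deterministic evaluation-mode forward pass (group normalisation has no
#' batch state and dropout is inference-disabled, so two forwards of the
#' same input are identical).
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param image numeric array height x width x 3 in [0, 1].
#' @return A \code{\linkS4class{PredictionBundle}}.
#' @export
forwardModel <- function(model, image) {
  H <- dim(image)[1L]
  W <- dim(image)[2L]
  X <- matrix(image, H * W, 3L)
  fw <- .forwardBatch(model, X, 1L, H, W)
  nP <- ncol(fw$partLogits)
  new("PredictionBundle",
      partLogits = array(fw$partLogits, c(H, W, nP)),
      partProbs = array(fw$partProbs, c(H, W, nP)),
      offsets = array(fw$offsets, c(H, W, 2L)),
      heatmap = matrix(fw$heatmap, H, W),
      fSeg = array(fw$fseg, c(H, W, ncol(fw$fseg))))
}

#' Per-pixel type map from the semantic-type variant
#'
#' @param model a model built with \code{variant = "semantic_type"}.
#' @param image numeric array height x width x 3.
#' @return Integer matrix of per-pixel type labels (0 background).
#' @export
semanticTypeMap <- function(model, image) {
  stopifnot(model$config$variant == "semantic_type")
  H <- dim(image)[1L]
  W <- dim(image)[2L]
  fw <- .forwardBatch(model, matrix(image, H * W, 3L), 1L, H, W)
  matrix(max.col(fw$typeProbs, ties.method = "first") - 1L, H, W)
}

# classifier forward on a masked feature map (npix x F matrix); returns
# caches for backward. `dropMask` is an optional per-channel dropout mask
# (already scaled), applied to the masked input during training.
.fwdClassifier <- function(model, fsegMasked, H, W, prior = NULL,
                           dropMask = NULL) {
  cfg <- model$config
  p <- model$params
  x <- fsegMasked
  if (!is.null(dropMask)) x <- x * rep(dropMask, each = nrow(x))
  h <- H; w <- W
  layers <- vector("list", 4L)
  for (k in 1:4) {
    cg <- .fwdCGR(p, sprintf("cls.c%d", k), x, 1L, h, w, cfg$normGroups)
    pl <- maxPoolForward(cg$out, 1L, h, w)
    layers[[k]] <- list(cgr = cg, pool = pl, H = h, W = w)
    x <- pl$out
    h <- h %/% 2L; w <- w %/% 2L
  }
  # global max pool over the remaining grid
  gidx <- integer(ncol(x))
  feat <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    gidx[j] <- which.max(x[, j])
    feat[j] <- x[gidx[j], j]
  }
  featIn <- feat
  if (cfg$usePrior) {
    if (is.null(prior) || length(prior) != cfg$nClasses)
      stop("model built with usePrior: supply a length-nClasses prior")
    v <- c(feat, as.numeric(prior))
    z1 <- as.numeric(v %*% p[["cls.fc1.W"]]) + p[["cls.fc1.b"]]
    a1 <- pmax(z1, 0)
    logits <- as.numeric(a1 %*% p[["cls.fc2.W"]]) + p[["cls.fc2.b"]]
    fc <- list(v = v, z1 = z1, a1 = a1)
  } else {
    if (!is.null(prior)) stop("model not built with usePrior")
    logits <- as.numeric(feat %*% p[["cls.fc1.W"]]) + p[["cls.fc1.b"]]
    fc <- list(v = feat)
  }
  e <- exp(logits - max(logits))
  list(probs = e / sum(e), logits = logits, layers = layers, gidx = gidx,
       fc = fc, gridN = nrow(x), gridC = ncol(x), H = H, W = W,
       dropMask = dropMask)
}

.bwdClassifier <- function(model, cache, dLogits, gacc) {
  cfg <- model$config
  p <- model$params
  if (cfg$usePrior) {
    .accGrad(gacc, "cls.fc2.W", outer(cache$fc$a1, dLogits))
    .accGrad(gacc, "cls.fc2.b", dLogits)
    da1 <- as.numeric(p[["cls.fc2.W"]] %*% dLogits) * (cache$fc$z1 > 0)
    .accGrad(gacc, "cls.fc1.W", outer(cache$fc$v, da1))
    .accGrad(gacc, "cls.fc1.b", da1)
    dv <- as.numeric(p[["cls.fc1.W"]] %*% da1)
    dFeat <- dv[seq_len(cache$gridC)]
  } else {
    .accGrad(gacc, "cls.fc1.W", outer(cache$fc$v, dLogits))
    .accGrad(gacc, "cls.fc1.b", dLogits)
    dFeat <- as.numeric(p[["cls.fc1.W"]] %*% dLogits)
  }
  dx <- matrix(0, cache$gridN, cache$gridC)
  dx[cbind(cache$gidx, seq_len(cache$gridC))] <- dFeat
  for (k in 4:1) {
    ly <- cache$layers[[k]]
    dp <- maxPoolBackward(dx, ly$pool, 1L, ly$H, ly$W, ncol(ly$cgr$out))
    dx <- .bwdCGR(p, sprintf("cls.c%d", k), dp, ly$cgr, 1L, ly$H, ly$W,
                  gacc)
  }
  if (!is.null(cache$dropMask)) dx <- dx * rep(cache$dropMask,
                                               each = nrow(dx))
  dx
}

#' Classify one instance from masked features
#'
#' Masks the segmentation feature map with the instance mask (pixel-wise
#' product broadcast over channels, hiding background and other
#' instances) and runs the shallow classifier: four conv-norm-relu layers
#' each followed by stride-2 max pooling, a global max pool, and the
#' fully connected head. With a presence prior, the prior vector is
#' concatenated to the pooled feature and passed through two FC layers.
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param fSeg numeric array height x width x channels (from
#'   \code{\link{forwardModel}}).
#' @param mask logical matrix with at least one TRUE pixel.
#' @param prior optional binary presence vector of length nClasses.
#' @return Numeric probability vector over the instrument types.
#' @export
classifyInstance <- function(model, fSeg, mask, prior = NULL) {
  if (model$config$variant == "semantic_type")
    stop("the semantic_type variant has no instance classifier")
  if (!any(mask)) stop("empty instance")
  d <- dim(fSeg)
  fm <- matrix(fSeg, d[1L] * d[2L], d[3L]) * as.numeric(mask)
  .fwdClassifier(model, fm, d[1L], d[2L], prior = prior)$probs
}
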
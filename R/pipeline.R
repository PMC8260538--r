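# Training: two-phase schedule (segmentation-decoder + encoder pretrain,
# then the joint objective), AdamW with a step learning-rate schedule,
# ground-truth teacher forcing of the classifier masks, channel dropout on
# the classifier input, clasper-visibility filtering of the classification
# task, and whole-image discard of frames without any visible clasper.

#' Training configuration
#'
#' Defaults follow the published schedule for the "full" preset (base
#' learning rate 1e-3 reduced to 1e-4 after 100 epochs, batch size 24,
#' 20 pretrain epochs, resize 512 x 640, crop 384 x 480, heatmap sigma
#' 20). The "tiny" preset scales the schedule to CPU scale: 30 epochs
#' with the learning-rate break at 24, 5 pretrain epochs, base rate 2e-3
#' (dropped tenfold), batch size 4 (group normalisation is batch-size
#' independent, so small batches buy more optimiser steps), no
#' resize/crop, and sigma 3.5.
#'
#' @param preset "tiny" or "full".
#' @param learningRate base learning rate.
#' @param lrAfter learning rate after the breakpoint.
#' @param lrBreakEpoch epoch after which the rate drops.
#' @param batchSize scenes per optimisation step.
#' @param pretrainEpochs epochs of segmentation-only pretraining.
#' @param totalEpochs total epochs (including pretraining).
#' @param resize,crop target sizes c(height, width) or NULL to skip.
#' @param augment list of toggles: \code{hflip} (random horizontal flip),
#'   \code{brightness} (max absolute intensity jitter, 0 disables).
#' @param teacherForcing use ground-truth instance masks as classifier
#'   input during training (default TRUE).
#' @param clasperMinPixels visibility threshold passed to the clasper
#'   filter.
#' @param sigma heatmap target sigma in pixels.
#' @param weightDecay AdamW decoupled weight decay.
#' @param gamma segmentation weight of the joint loss.
#' @param alpha,beta focal loss exponents.
#' @param valEvery validate every this many epochs (0 = only at the end).
#' @param seed RNG seed controlling shuffling, dropout and augmentation.
#' @return A validated configuration list.
#' @export
trainConfig <- function(preset = c("tiny", "full"), learningRate = NULL,
                        lrAfter = NULL, lrBreakEpoch = NULL,
                        batchSize = NULL, pretrainEpochs = NULL,
                        totalEpochs = NULL, resize = NULL, crop = NULL,
                        augment = list(hflip = TRUE, brightness = 0),
                        teacherForcing = TRUE, clasperMinPixels = 10L,
                        sigma = NULL, weightDecay = 1e-4, gamma = 10,
                        alpha = 2, beta = 4, valEvery = 0L, seed = 1L) {
  preset <- match.arg(preset)
  tiny <- preset == "tiny"
  if (is.null(learningRate)) learningRate <- if (tiny) 2e-3 else 1e-3
  if (is.null(lrAfter)) lrAfter <- learningRate / 10
  if (is.null(lrBreakEpoch)) lrBreakEpoch <- if (tiny) 24L else 100L
  if (is.null(batchSize)) batchSize <- if (tiny) 4L else 24L
  if (is.null(pretrainEpochs)) pretrainEpochs <- if (tiny) 5L else 20L
  if (is.null(totalEpochs)) totalEpochs <- if (tiny) 30L else 200L
  if (is.null(sigma)) sigma <- if (tiny) 3.5 else 20
  if (!tiny && is.null(resize)) resize <- c(512L, 640L)
  if (!tiny && is.null(crop)) crop <- c(384L, 480L)
  if (!is.null(crop) && !is.null(resize))
    stopifnot(all(crop <= resize))
  stopifnot(pretrainEpochs <= totalEpochs, batchSize >= 1L,
            learningRate > 0, lrAfter > 0, sigma > 0)
  list(preset = preset, learningRate = learningRate, lrAfter = lrAfter,
       lrBreakEpoch = as.integer(lrBreakEpoch),
       batchSize = as.integer(batchSize),
       pretrainEpochs = as.integer(pretrainEpochs),
       totalEpochs = as.integer(totalEpochs), resize = resize, crop = crop,
       augment = augment, teacherForcing = teacherForcing,
       clasperMinPixels = as.integer(clasperMinPixels), sigma = sigma,
       weightDecay = weightDecay, gamma = gamma, alpha = alpha,
       beta = beta, valEvery = as.integer(valEvery),
       seed = as.integer(seed))
}

#' Learning rate at a given epoch
#'
#' Step schedule: the base rate up to and including the break epoch, the
#' reduced rate afterwards.
#'
#' @param epoch 1-based epoch.
#' @param config a \code{\link{trainConfig}}.
#' @return Numeric learning rate.
#' @export
lrSchedule <- function(epoch, config) {
  if (epoch <= config$lrBreakEpoch) config$learningRate else config$lrAfter
}

#' Clasper-visibility filtering for the classification task
#'
#' Instances whose clasper is not visible are dropped from the
#' classification loss; images without any visible clasper are discarded
#' from training entirely (all losses). Evaluation never filters.
#'
#' @param scenes list of \code{\linkS4class{LabeledScene}} objects.
#' @return List with \code{scenes} (the kept scenes) and \code{instances}
#'   (per kept scene, the integer ids eligible for classification).
#' @export
filterClassificationBatch <- function(scenes) {
  keptScenes <- list()
  keptIds <- list()
  for (sc in scenes) {
    vis <- clasperVisible(sc)
    ids <- as.integer(names(vis)[vis])
    if (!length(ids)) next
    keptScenes[[length(keptScenes) + 1L]] <- sc
    keptIds[[length(keptIds) + 1L]] <- ids
  }
  list(scenes = keptScenes, instances = keptIds)
}

#' Horizontal flip of a scene
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @return The mirrored scene (types and visibility unchanged).
#' @export
hflipScene <- function(scene) {
  W <- ncol(instanceMap(scene))
  img <- sceneImage(scene)[, W:1, , drop = FALSE]
  new("LabeledScene", image = img,
      instanceMap = instanceMap(scene)[, W:1],
      partMap = partMap(scene)[, W:1],
      types = instrumentTypes(scene),
      clasperVisible = clasperVisible(scene), frameId = frameId(scene))
}

#' Nearest-neighbour resize of a scene
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param height,width target size.
#' @return The resized scene (label maps stay crisp under
#'   nearest-neighbour sampling).
#' @export
resizeScene <- function(scene, height, width) {
  H <- nrow(instanceMap(scene))
  W <- ncol(instanceMap(scene))
  ri <- pmin(pmax(round(seq(1, H, length.out = height)), 1L), H)
  ci <- pmin(pmax(round(seq(1, W, length.out = width)), 1L), W)
  img <- sceneImage(scene)[ri, ci, , drop = FALSE]
  new("LabeledScene", image = img,
      instanceMap = instanceMap(scene)[ri, ci],
      partMap = partMap(scene)[ri, ci],
      types = instrumentTypes(scene),
      clasperVisible = clasperVisible(scene), frameId = frameId(scene))
}

#' Crop a scene
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param height,width crop size.
#' @param top,left 1-based crop origin (random when NULL).
#' @return The cropped scene; instances cropped out entirely keep their
#'   annotation entries but no pixels.
#' @export
cropScene <- function(scene, height, width, top = NULL, left = NULL) {
  H <- nrow(instanceMap(scene))
  W <- ncol(instanceMap(scene))
  stopifnot(height <= H, width <= W)
  if (is.null(top)) top <- sample.int(H - height + 1L, 1L)
  if (is.null(left)) left <- sample.int(W - width + 1L, 1L)
  rows <- top:(top + height - 1L)
  cols <- left:(left + width - 1L)
  new("LabeledScene", image = sceneImage(scene)[rows, cols, , drop = FALSE],
      instanceMap = instanceMap(scene)[rows, cols],
      partMap = partMap(scene)[rows, cols],
      types = instrumentTypes(scene),
      clasperVisible = clasperVisible(scene), frameId = frameId(scene))
}

#' Binary presence prior from a scene's annotations
#'
#' The kinematics-style prior: a binary vector over the type vocabulary
#' marking which instrument types are mounted (present) in the frame.
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param nClasses number of types.
#' @return Binary numeric vector of length \code{nClasses}.
#' @export
priorFromScene <- function(scene, nClasses = 7L) {
  v <- numeric(nClasses)
  v[unique(instrumentTypes(scene))] <- 1
  v
}

# ---- loss gradients on batched outputs ---------------------------------

# cross-entropy + per-frame soft DICE on part logits; returns value and
# gradient wrt logits
.segLossGrad <- function(partProbs, targetVec, B, npix, diceEps = 1) {
  nc <- ncol(partProbs)
  Ntot <- B * npix
  idx <- cbind(seq_len(Ntot), targetVec + 1L)
  ceVal <- -mean(log(pmax(partProbs[idx], 1e-12)))
  G <- matrix(0, Ntot, nc)
  G[idx] <- 1
  dLogitsCE <- (partProbs - G) / Ntot
  diceVal <- 0
  dP <- matrix(0, Ntot, nc)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * npix + 1L):(b * npix)
    pb <- partProbs[rows, , drop = FALSE]
    gb <- G[rows, , drop = FALSE]
    num <- 2 * colSums(pb * gb) + diceEps
    den <- colSums(pb) + colSums(gb) + diceEps
    diceVal <- diceVal + (1 - mean(num / den)) / B
    # d(num/den)/dp = (2 g * den - num) / den^2
    dP[rows, ] <- -(2 * gb * rep(den, each = npix) -
                      rep(num, each = npix)) /
      rep(den^2, each = npix) / (B * nc)
  }
  dLogitsDice <- partProbs * (dP - rowSums(dP * partProbs))
  list(value = ceVal + diceVal, dLogits = dLogitsCE + dLogitsDice)
}

.offsetLossGrad <- function(predOff, targetOff, fgVec, B, npix) {
  diff <- predOff - targetOff
  dPred <- matrix(0, nrow(predOff), 2L)
  val <- 0
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * npix + 1L):(b * npix)
    m <- fgVec[rows]
    n <- sum(m)
    if (n == 0L) next
    d <- diff[rows, , drop = FALSE]
    val <- val + sum(abs(d[m, ])) / n / B
    s <- sign(d) * m
    dPred[rows, ] <- s / (n * B)
  }
  list(value = val, dPred = dPred)
}

.centroidLossGrad <- function(hmPred, hmTarget, nInstPerFrame, B, npix,
                              alpha = 2, beta = 4) {
  p <- pmin(pmax(hmPred, 1e-6), 1 - 1e-6)
  y <- hmTarget
  pos <- y >= 1 - 1e-12
  val <- 0
  dP <- numeric(length(p))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * npix + 1L):(b * npix)
    N <- max(1, nInstPerFrame[b])
    pb <- p[rows]
    yb <- y[rows]
    pe <- pos[rows]
    term <- numeric(npix)
    dterm <- numeric(npix)
    term[pe] <- (1 - pb[pe])^alpha * log(pb[pe])
    dterm[pe] <- -alpha * (1 - pb[pe])^(alpha - 1) * log(pb[pe]) +
      (1 - pb[pe])^alpha / pb[pe]
    ne <- !pe
    term[ne] <- (1 - yb[ne])^beta * pb[ne]^alpha * log(1 - pb[ne])
    dterm[ne] <- (1 - yb[ne])^beta *
      (alpha * pb[ne]^(alpha - 1) * log(1 - pb[ne]) - pb[ne]^alpha /
         (1 - pb[ne]))
    val <- val - sum(term) / (N * B)
    dP[rows] <- -dterm / (N * B)
  }
  list(value = val, dP = dP)
}

# ---- the training step -------------------------------------------------

.sceneTensor <- function(scene) {
  d <- dim(sceneImage(scene))
  matrix(sceneImage(scene), d[1L] * d[2L], 3L)
}

.trainStep <- function(model, scenes, targets, clsIds, cfg, phase,
                       classWeights, priors = NULL, hook = NULL) {
  mcfg <- model$config
  B <- length(scenes)
  H <- nrow(instanceMap(scenes[[1L]]))
  W <- ncol(instanceMap(scenes[[1L]]))
  npix <- H * W
  X <- do.call(rbind, lapply(scenes, .sceneTensor))
  p <- model$params
  gacc <- new.env(parent = emptyenv())
  enc <- .fwdEncoder(model, X, B, H, W)
  single <- mcfg$variant == "single_decoder"
  segName <- if (single) "dec.shared" else "dec.seg"
  dseg <- .fwdDecoder(model, segName, enc, B)
  fseg <- dseg$out
  if (!is.finite(sum(fseg)))
    stop("non-finite activations: training diverged (reduce the learning rate)")
  partLogits <- .fwd1x1(p, "head.part", fseg)
  partProbsM <- softmaxRows(partLogits)
  targetVec <- unlist(lapply(targets, function(t) {
    tv <- as.integer(partTarget(t))
    if (mcfg$variant == "binary_seg") tv <- as.integer(tv != 0L)
    tv
  }), use.names = FALSE)
  seg <- .segLossGrad(partProbsM, targetVec, B, npix)
  segW <- if (phase == "pretrain") 1 else cfg$gamma
  dfseg <- .bwd1x1(p, "head.part", fseg, seg$dLogits * segW, gacc)
  lossOff <- 0; lossHm <- 0; lossType <- 0
  offDec <- NULL; doffOut <- NULL
  typeDec <- NULL
  if (phase != "pretrain") {
    offName <- if (single) "dec.shared" else "dec.off"
    offDec <- if (single) dseg else .fwdDecoder(model, "dec.off", enc, B)
    offFeat <- offDec$out
    offScale <- .resolveOffsetScale(mcfg, H, W)
    offRaw <- .fwd1x1(p, "head.off", offFeat)
    hmLogit <- as.numeric(.fwd1x1(p, "head.hm", offFeat))
    hmPred <- sigmoid(hmLogit)
    fgVec <- unlist(lapply(targets, function(t)
      as.logical(foregroundMask(t))), use.names = FALSE)
    offT <- do.call(rbind, lapply(targets, function(t) {
      o <- offsetTarget(t)
      cbind(as.numeric(o[, , 1L]), as.numeric(o[, , 2L]))
    }))
    hmT <- unlist(lapply(targets, function(t)
      as.numeric(heatmapTarget(t))), use.names = FALSE)
    nInst <- vapply(targets, function(t) nrow(centroidList(t)), integer(1L))
    off <- .offsetLossGrad(offRaw * offScale, offT, fgVec, B, npix)
    hm <- .centroidLossGrad(hmPred, hmT, nInst, B, npix, cfg$alpha,
                            cfg$beta)
    lossOff <- off$value
    lossHm <- hm$value
    dOffFeat <- .bwd1x1(p, "head.off", offFeat, off$dPred * offScale, gacc)
    dHmLogit <- matrix(hm$dP * hmPred * (1 - hmPred), ncol = 1L)
    dOffFeat <- dOffFeat + .bwd1x1(p, "head.hm", offFeat, dHmLogit, gacc)
    doffOut <- dOffFeat
    if (mcfg$variant == "semantic_type") {
      typeDec <- .fwdDecoder(model, "dec.type", enc, B)
      typeLogits <- .fwd1x1(p, "head.type", typeDec$out)
      typeProbs <- softmaxRows(typeLogits)
      typeTarget <- unlist(lapply(seq_len(B), function(b) {
        as.integer(typeLabelMap(scenes[[b]]))
      }), use.names = FALSE)
      idx <- cbind(seq_along(typeTarget), typeTarget + 1L)
      lossType <- -mean(log(pmax(typeProbs[idx], 1e-12)))
      Gt <- matrix(0, length(typeTarget), ncol(typeProbs))
      Gt[idx] <- 1
      dTypeOut <- .bwd1x1(p, "head.type", typeDec$out,
                          (typeProbs - Gt) / length(typeTarget), gacc)
      typeDec$dOut <- dTypeOut
    } else {
      # per-instance classification with teacher forcing on GT masks
      instList <- list()
      for (b in seq_len(B)) {
        for (id in clsIds[[b]]) {
          instList[[length(instList) + 1L]] <-
            list(b = b, id = id,
                 class = instrumentTypes(scenes[[b]])[[as.character(id)]])
        }
      }
      M <- length(instList)
      if (M > 0L) {
        for (it in instList) {
          rows <- ((it$b - 1L) * npix + 1L):(it$b * npix)
          maskVec <- as.numeric(instanceMap(scenes[[it$b]]) == it$id)
          if (!is.null(hook)) hook(it$b, it$id, maskVec)
          fm <- fseg[rows, , drop = FALSE] * maskVec
          dropMask <- NULL
          if (mcfg$dropoutFseg > 0) {
            keep <- runif(ncol(fm)) >= mcfg$dropoutFseg
            if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
            dropMask <- keep / (1 - mcfg$dropoutFseg)
          }
          pr <- if (mcfg$usePrior) priors[[it$b]] else NULL
          cl <- .fwdClassifier(model, fm, H, W, prior = pr,
                               dropMask = dropMask)
          w <- classWeights[it$class]
          lossType <- lossType - w * log(max(cl$probs[it$class], 1e-12)) / M
          dLogits <- cl$probs
          dLogits[it$class] <- dLogits[it$class] - 1
          dLogits <- dLogits * w / M
          dxm <- .bwdClassifier(model, cl, dLogits, gacc)
          dfseg[rows, ] <- dfseg[rows, ] + dxm * maskVec
        }
      }
    }
  }
  # decoder / encoder backward
  if (single && !is.null(doffOut)) dfseg <- dfseg + doffOut
  bseg <- .bwdDecoder(model, segName, dseg, enc, dfseg, B, gacc)
  dBottom <- bseg$dBottom
  dSkips <- bseg$dSkips
  addSkips <- function(a, b) {
    for (s in seq_along(b)) {
      if (is.null(b[[s]])) next
      if (is.null(a[[s]])) a[[s]] <- b[[s]] else a[[s]] <- a[[s]] + b[[s]]
    }
    a
  }
  if (!single && !is.null(doffOut)) {
    boff <- .bwdDecoder(model, "dec.off", offDec, enc, doffOut, B, gacc)
    dBottom <- dBottom + boff$dBottom
    dSkips <- addSkips(dSkips, boff$dSkips)
  }
  if (!is.null(typeDec)) {
    btype <- .bwdDecoder(model, "dec.type", typeDec, enc, typeDec$dOut, B,
                         gacc)
    dBottom <- dBottom + btype$dBottom
    dSkips <- addSkips(dSkips, btype$dSkips)
  }
  .bwdEncoder(model, enc, dBottom, dSkips, B, gacc)
  segVal <- seg$value
  joint <- lossType + lossOff + lossHm + cfg$gamma * segVal
  list(grads = as.list(gacc), lossSeg = segVal, lossOff = lossOff,
       lossHm = lossHm, lossType = lossType,
       loss = if (phase == "pretrain") segVal else joint)
}

#' Train a model
#'
#' Phase 1 (\code{pretrainEpochs}): only the encoder and the segmentation
#' decoder are optimised, on the segmentation loss alone. Phase 2: the
#' joint objective L_type + L_offset + L_centroid + gamma L_seg,
#' end-to-end, with ground-truth instance masks fed to the classifier
#' (teacher forcing) and channel dropout on its input features.
#' Instances without a visible clasper are excluded from the
#' classification loss; frames with no visible clasper at all are
#' discarded from training entirely. Class weights are the
#' mean-normalised inverse type occurrence counts of the (filtered)
#' training instances. Fully deterministic given \code{config$seed}.
#'
#' @param mConfig a \code{\link{modelConfig}}.
#' @param tConfig a \code{\link{trainConfig}}.
#' @param scenes training scenes (equal sizes).
#' @param valScenes optional held-out scenes for validation.
#' @param verbose print per-epoch losses.
#' @param hook optional function(frameIndex, instanceId, maskVector)
#'   called with every classifier input mask (instrumentation).
#' @return A list: \code{model} (final), \code{bestModel} (best
#'   validation types accuracy; equals final when never validated),
#'   \code{log} (per-epoch data.frame), \code{classWeights},
#'   \code{valHistory}.
#' @export
trainModel <- function(mConfig, tConfig, scenes, valScenes = NULL,
                       verbose = FALSE, hook = NULL) {
  .withSeed(tConfig$seed, .trainModelImpl(mConfig, tConfig, scenes,
                                          valScenes, verbose, hook))
}

.trainModelImpl <- function(mConfig, tConfig, scenes, valScenes, verbose,
                            hook) {
  if (!is.null(tConfig$resize))
    scenes <- lapply(scenes, function(s)
      resizeScene(s, tConfig$resize[1L], tConfig$resize[2L]))
  filt <- filterClassificationBatch(scenes)
  scenes <- filt$scenes
  clsIds <- filt$instances
  if (!length(scenes)) stop("no trainable scenes after clasper filtering")
  counts <- integer(mConfig$nClasses)
  for (i in seq_along(scenes)) {
    tps <- instrumentTypes(scenes[[i]])
    for (id in clsIds[[i]]) {
      cl <- tps[[as.character(id)]]
      counts[cl] <- counts[cl] + 1L
    }
  }
  classWeights <- classWeightsFromCounts(pmax(counts, 0L))
  model <- buildModel(mConfig, seed = sample.int(1e6, 1L))
  state <- adamwInit(model$params)
  targetsCache <- lapply(scenes, buildTargets, sigma = tConfig$sigma)
  flipCache <- vector("list", length(scenes))
  priors <- lapply(scenes, priorFromScene, nClasses = mConfig$nClasses)
  log <- list()
  valHistory <- list()
  bestModel <- NULL
  bestScore <- -Inf
  nB <- ceiling(length(scenes) / tConfig$batchSize)
  for (epoch in seq_len(tConfig$totalEpochs)) {
    phase <- if (epoch <= tConfig$pretrainEpochs) "pretrain" else "joint"
    lr <- lrSchedule(epoch, tConfig)
    ord <- sample.int(length(scenes))
    ep <- c(lossSeg = 0, lossOff = 0, lossHm = 0, lossType = 0, loss = 0)
    for (bi in seq_len(nB)) {
      take <- ord[((bi - 1L) * tConfig$batchSize + 1L):
                    min(bi * tConfig$batchSize, length(scenes))]
      bScenes <- scenes[take]
      bTargets <- targetsCache[take]
      bIds <- clsIds[take]
      bPriors <- priors[take]
      if (isTRUE(tConfig$augment$hflip)) {
        flip <- runif(length(take)) < 0.5
        for (j in which(flip)) {
          i <- take[j]
          if (is.null(flipCache[[i]])) {
            fs <- hflipScene(scenes[[i]])
            flipCache[[i]] <- list(scene = fs,
                                   targets = buildTargets(fs,
                                                          tConfig$sigma))
          }
          bScenes[[j]] <- flipCache[[i]]$scene
          bTargets[[j]] <- flipCache[[i]]$targets
        }
      }
      if (!is.null(tConfig$crop)) {
        for (j in seq_along(bScenes)) {
          bScenes[[j]] <- cropScene(bScenes[[j]], tConfig$crop[1L],
                                    tConfig$crop[2L])
          bTargets[[j]] <- buildTargets(bScenes[[j]], tConfig$sigma)
        }
      }
      br <- if (is.numeric(tConfig$augment$brightness) &&
                tConfig$augment$brightness > 0) {
        tConfig$augment$brightness
      } else 0
      if (br > 0) {
        for (j in seq_along(bScenes)) {
          sc <- bScenes[[j]]
          img <- pmin(pmax(sceneImage(sc) + runif(1, -br, br), 0), 1)
          sc@image <- img
          bScenes[[j]] <- sc
        }
      }
      st <- .trainStep(model, bScenes, bTargets, bIds, tConfig, phase,
                       classWeights, priors = bPriors, hook = hook)
      if (!is.finite(st$loss))
        stop(sprintf("non-finite loss at epoch %d batch %d", epoch, bi))
      upd <- adamwStep(model$params, st$grads, state, lr,
                       decay = tConfig$weightDecay)
      model$params <- upd$params
      state <- upd$state
      ep <- ep + c(st$lossSeg, st$lossOff, st$lossHm, st$lossType,
                   st$loss) / nB
    }
    log[[epoch]] <- data.frame(epoch = epoch, phase = phase, lr = lr,
                               lossSeg = ep[["lossSeg"]],
                               lossOff = ep[["lossOff"]],
                               lossHm = ep[["lossHm"]],
                               lossType = ep[["lossType"]],
                               loss = ep[["loss"]])
    if (verbose)
      message(sprintf(
        "epoch %3d [%s] loss %.4f (seg %.4f off %.4f hm %.4f type %.4f)",
        epoch, phase, ep[["loss"]], ep[["lossSeg"]], ep[["lossOff"]],
        ep[["lossHm"]], ep[["lossType"]]))
    doVal <- !is.null(valScenes) &&
      ((tConfig$valEvery > 0L && epoch %% tConfig$valEvery == 0L) ||
         epoch == tConfig$totalEpochs)
    if (doVal) {
      vs <- validateModel(model, valScenes,
                          usePrior = mConfig$usePrior)
      vs$epoch <- epoch
      valHistory[[length(valHistory) + 1L]] <- vs
      score <- if (is.na(vs$typeAccuracy)) vs$foregroundIoU
               else vs$typeAccuracy + vs$foregroundIoU
      if (score > bestScore) {
        bestScore <- score
        bestModel <- model
      }
      if (verbose)
        message(sprintf("  val: fg IoU %.3f, type acc %.3f",
                        vs$foregroundIoU, vs$typeAccuracy))
    }
  }
  if (is.null(bestModel)) bestModel <- model
  list(model = model, bestModel = bestModel,
       log = do.call(rbind, log), classWeights = classWeights,
       valHistory = valHistory)
}

#' Binary foreground IoU of a predicted part map
#'
#' @param predPartMap integer matrix of predicted part labels.
#' @param gtPartMap integer matrix of reference part labels.
#' @return IoU of the non-background masks (1 when both are empty).
#' @export
binaryForegroundIoU <- function(predPartMap, gtPartMap) {
  p <- predPartMap != 0L
  g <- gtPartMap != 0L
  u <- sum(p | g)
  if (u == 0L) return(1)
  sum(p & g) / u
}

#' Per-instance type accuracy
#'
#' Every ground-truth instance is matched to the predicted instance of
#' highest mask IoU (ignoring classes); it counts as correct when a match
#' exists and carries the right type label. Unmatched ground-truth
#' instances count as wrong, so detection failures are penalised.
#'
#' @param results list of \code{\linkS4class{InstanceResult}} objects.
#' @param scenes matching list of \code{\linkS4class{LabeledScene}}s.
#' @return List with \code{accuracy}, \code{nCorrect}, \code{nInstances}.
#' @export
instanceTypeAccuracy <- function(results, scenes) {
  nGT <- 0L
  nCorrect <- 0L
  for (i in seq_along(scenes)) {
    ginst <- instanceMap(scenes[[i]])
    tps <- instrumentTypes(scenes[[i]])
    pinst <- instanceMap(results[[i]])
    labs <- classLabels(results[[i]])
    for (key in names(tps)) {
      nGT <- nGT + 1L
      g <- ginst == as.integer(key)
      if (!length(labs)) next
      ious <- vapply(seq_along(labs), function(j)
        .maskIoU(pinst == j, g), numeric(1L))
      best <- which.max(ious)
      if (ious[best] > 0 && labs[best] == tps[[key]])
        nCorrect <- nCorrect + 1L
    }
  }
  list(accuracy = if (nGT) nCorrect / nGT else NA_real_,
       nCorrect = nCorrect, nInstances = nGT)
}

#' Validate a model on held-out scenes
#'
#' Runs full inference per scene and reports mean binary foreground IoU
#' (following the challenge protocol, the mean is over frames with at
#' least one instrument present in the ground truth), per-instance type
#' accuracy, and the mIoU/mAP report of \code{\link{evaluateScenes}}.
#' No clasper filtering is applied.
#'
#' @param model a trained model.
#' @param scenes held-out scenes.
#' @param infConfig an \code{\link{inferenceConfig}}.
#' @param usePrior supply each scene's presence prior to the classifier
#'   (only for models built with \code{usePrior}).
#' @return List with \code{foregroundIoU}, \code{typeAccuracy},
#'   \code{report} (an \code{\linkS4class{EvalReport}}).
#' @export
validateModel <- function(model, scenes, infConfig = inferenceConfig(),
                          usePrior = FALSE) {
  results <- vector("list", length(scenes))
  partPreds <- vector("list", length(scenes))
  fgIoU <- rep(NA_real_, length(scenes))
  semantic <- model$config$variant == "semantic_type"
  for (i in seq_along(scenes)) {
    img <- sceneImage(scenes[[i]])
    pred <- forwardModel(model, img)
    pp <- partProbs(pred)
    d <- dim(pp)
    pm <- matrix(max.col(matrix(pp, d[1L] * d[2L], d[3L]),
                         ties.method = "first") - 1L, d[1L], d[2L])
    partPreds[[i]] <- pm
    if (any(partMap(scenes[[i]]) != 0L))  # present-in-GT protocol
      fgIoU[i] <- binaryForegroundIoU(pm, partMap(scenes[[i]]))
    prior <- if (usePrior) priorFromScene(scenes[[i]],
                                          model$config$nClasses) else NULL
    results[[i]] <- predictFromBundle(model, pred,
                                      prior = prior,
                                      classify = !semantic)
  }
  if (semantic) {
    typeMaps <- lapply(scenes, function(s)
      semanticTypeMap(model, sceneImage(s)))
    gtMaps <- lapply(scenes, typeLabelMap)
    perFrame <- mapply(frameMIoU, typeMaps, gtMaps)
    tm <- mean(perFrame[!is.na(perFrame)])
    report <- new("EvalReport",
                  perFrameMIoU = perFrame, typesMIoU = tm,
                  partsMIoU = datasetMIoU(partPreds,
                                          lapply(scenes, partMap),
                                          nLabels = 4L),
                  mAP5095 = NA_real_,
                  perClassAP = setNames(numeric(0), character(0)),
                  nFrames = length(scenes))
    acc <- NA_real_
  } else {
    report <- evaluateScenes(results, scenes, partPreds = partPreds,
                             nClasses = model$config$nClasses)
    acc <- instanceTypeAccuracy(results, scenes)$accuracy
  }
  list(foregroundIoU = mean(fgIoU, na.rm = TRUE), typeAccuracy = acc,
       report = report)
}

#' Train and compare architecture variants
#'
#' Trains each variant with identical data, seeds and budgets and reports
#' the held-out types mIoU (and mask mAP where instances are defined;
#' the semantic_type variant has no instance output, so its mAP is NA).
#'
#' @param variants character vector of \code{\link{modelConfig}} variants.
#' @param scenes training scenes.
#' @param valScenes evaluation scenes.
#' @param mConfig base model configuration (its variant field is
#'   overridden).
#' @param tConfig shared training configuration.
#' @return data.frame with one row per variant: typesMIoU, partsMIoU,
#'   mAP, foregroundIoU, typeAccuracy.
#' @export
runAblation <- function(variants, scenes, valScenes,
                        mConfig = modelConfig(), tConfig = trainConfig()) {
  stopifnot(all(variants %in% c("proposed", "semantic_type",
                                "single_decoder", "binary_seg")))
  rows <- lapply(variants, function(v) {
    mc <- mConfig
    mc$variant <- v
    fit <- trainModel(mc, tConfig, scenes)
    val <- validateModel(fit$model, valScenes)
    data.frame(variant = v,
               typesMIoU = typesMIoU(val$report),
               partsMIoU = if (v == "binary_seg") NA_real_
                           else partsMIoU(val$report),
               mAP = maskMAPScore(val$report),
               foregroundIoU = val$foregroundIoU,
               typeAccuracy = val$typeAccuracy)
  })
  do.call(rbind, rows)
}
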
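# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (per-pixel loops, exhaustive enumeration, direct
# formula evaluation) and never share code with the implementation paths
# they check.

# exhaustive per-pixel nearest-centroid search (ties -> smallest index)
oracleAssign <- function(foregroundMask, offsets, centroids) {
  H <- nrow(foregroundMask)
  W <- ncol(foregroundMask)
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (!foregroundMask[r, c]) next
      pr <- r - offsets[r, c, 1L]
      pc <- c - offsets[r, c, 2L]
      best <- 0L
      bestD <- Inf
      for (i in seq_len(nrow(centroids))) {
        d <- sqrt((pr - centroids[i, 1L])^2 + (pc - centroids[i, 2L])^2)
        if (d < bestD - 1e-12) {
          bestD <- d
          best <- i
        }
      }
      out[r, c] <- best
    }
  }
  out
}

# interpolated AP computed from an explicit matching, written
# independently of the package's implementation
oracleAPFromMatch <- function(tpFlags, nGT) {
  if (nGT == 0L) return(NA_real_)
  if (!length(tpFlags)) return(0)
  ap <- 0
  for (i in seq_along(tpFlags)) {
    if (!tpFlags[i]) next
    rec_i <- sum(tpFlags[1:i]) / nGT
    rec_prev <- if (sum(tpFlags[1:i]) == 1L) 0 else
      (sum(tpFlags[1:i]) - 1L) / nGT
    # precision attainable at recall >= rec_i
    pbest <- 0
    for (j in i:length(tpFlags)) {
      pbest <- max(pbest, sum(tpFlags[1:j]) / j)
    }
    ap <- ap + (rec_i - rec_prev) * pbest
  }
  ap
}

# brute-force mAP: for every class and threshold, enumerate all injective
# prediction-to-ground-truth matchings (same class and frame, IoU >= thr)
# and take the best attainable AP
oracleMaskMAP <- function(predictions, gts, thresholds = seq(0.5, 0.95,
                                                            by = 0.05)) {
  iou <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 0 else sum(a & b) / u
  }
  gtClasses <- vapply(gts, function(g) g$class, numeric(1L))
  classes <- sort(unique(gtClasses))
  perClass <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    pIdx <- which(vapply(predictions, function(p) p$class, numeric(1L)) == cl)
    pIdx <- pIdx[order(-vapply(predictions[pIdx], function(p) p$score,
                               numeric(1L)))]
    gIdx <- which(gtClasses == cl)
    aps <- vapply(thresholds, function(thr) {
      # candidate gts per prediction
      cand <- lapply(pIdx, function(pi) {
        ok <- integer(0)
        for (gi in gIdx) {
          if (predictions[[pi]]$frame == gts[[gi]]$frame &&
              iou(predictions[[pi]]$mask, gts[[gi]]$mask) >= thr)
            ok <- c(ok, gi)
        }
        ok
      })
      bestAP <- -1
      rec <- function(i, used, flags) {
        if (i > length(pIdx)) {
          ap <- oracleAPFromMatch(flags, length(gIdx))
          if (ap > bestAP) bestAP <<- ap
          return(invisible())
        }
        rec(i + 1L, used, c(flags, FALSE))            # leave unmatched
        for (gi in setdiff(cand[[i]], used)) {
          rec(i + 1L, c(used, gi), c(flags, TRUE))
        }
      }
      rec(1L, integer(0), logical(0))
      if (bestAP < 0) 0 else bestAP
    }, numeric(1L))
    perClass[ci] <- mean(aps)
  }
  mean(perClass)
}

# a small hand-checkable scene: one L-shaped instrument of class `type`
makeToyScene <- function(H = 16L, W = 20L, type = 2L, id = 1L) {
  inst <- matrix(0L, H, W)
  part <- matrix(0L, H, W)
  inst[8:10, 3:14] <- id
  part[8:10, 3:10] <- 1L   # shaft
  part[8:10, 11:12] <- 2L  # wrist
  part[8:10, 13:14] <- 3L  # clasper
  LabeledScene(array(0.5, c(H, W, 3L)), inst, part,
               types = setNames(type, as.character(id)),
               clasperVisible = setNames(TRUE, as.character(id)),
               frameId = "toy")
}

# prediction bundle that reproduces a scene's targets exactly (oracle
# network): near-one-hot part logits, exact offsets, the Gaussian target
# as heatmap, and a trivial feature map
bundleFromTargets <- function(scene, tb, bigLogit = 50) {
  H <- nrow(partMap(scene))
  W <- ncol(partMap(scene))
  nP <- 5L
  logits <- array(0, c(H, W, nP))
  for (k in seq_len(nP)) {
    logits[, , k] <- ifelse(partTarget(tb) == k - 1L, bigLogit, -bigLogit)
  }
  probs <- array(apply(logits, c(1, 2), function(z) exp(z - max(z)) /
                         sum(exp(z - max(z)))), c(nP, H, W))
  probs <- aperm(probs, c(2, 3, 1))
  new("PredictionBundle", partLogits = logits, partProbs = probs,
      offsets = offsetTarget(tb),
      heatmap = pmin(pmax(heatmapTarget(tb), 1e-6), 1 - 1e-6),
      fSeg = array(1, c(H, W, 4L)))
}
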
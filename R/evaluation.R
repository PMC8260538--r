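# Challenge-style scoring: present-in-ground-truth mIoU and COCO-style
# mask mAP over IoU thresholds 0.50:0.95.

#' Per-frame mean IoU over classes present in the ground truth
#'
#' For every non-background label present in the ground-truth map, the
#' intersection-over-union with the prediction is computed; the frame
#' score is the mean over those labels. Labels predicted but absent from
#' the ground truth are excluded: under the challenge protocol the mIoU
#' is computed only where an instrument is present in the ground truth.
#'
#' @param predLabelMap,gtLabelMap integer matrices of equal shape with
#'   labels in 0..nLabels.
#' @param nLabels number of non-background labels.
#' @return The frame mIoU, or NA when no non-background label is present
#'   in the ground truth.
#' @export
frameMIoU <- function(predLabelMap, gtLabelMap, nLabels = 7L) {
  if (!identical(dim(predLabelMap), dim(gtLabelMap)))
    stop("shape mismatch")
  present <- setdiff(sort(unique(as.integer(gtLabelMap))), 0L)
  if (!length(present)) return(NA_real_)
  ious <- vapply(present, function(lab) {
    p <- predLabelMap == lab
    g <- gtLabelMap == lab
    sum(p & g) / sum(p | g)
  }, numeric(1L))
  mean(ious)
}

#' Dataset mIoU
#'
#' Mean of \code{\link{frameMIoU}} over the frames where it is defined
#' (at least one label present in the ground truth).
#'
#' @param preds,gts lists of label matrices, same length.
#' @param nLabels number of non-background labels.
#' @return Scalar mIoU.
#' @export
datasetMIoU <- function(preds, gts, nLabels = 7L) {
  stopifnot(length(preds) == length(gts))
  scores <- mapply(frameMIoU, preds, gts, MoreArgs = list(nLabels = nLabels))
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no frame has a present label")
  mean(scores)
}

#' Paint a label map from an instance result or scene
#'
#' Builds the per-pixel type map used by the mIoU protocol: each
#' instance's pixels are painted with its (predicted or ground-truth)
#' type label.
#'
#' @param x an \code{\linkS4class{InstanceResult}} or
#'   \code{\linkS4class{LabeledScene}}.
#' @return Integer matrix of type labels (0 background).
#' @export
typeLabelMap <- function(x) {
  inst <- instanceMap(x)
  out <- matrix(0L, nrow(inst), ncol(inst))
  if (is(x, "InstanceResult")) {
    labs <- classLabels(x)
    for (i in seq_along(labs)) out[inst == i] <- labs[i]
  } else {
    tps <- instrumentTypes(x)
    for (key in names(tps)) out[inst == as.integer(key)] <- tps[[key]]
  }
  out
}

# IoU between two logical masks
.maskIoU <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# all-point interpolated average precision from TP flags in score order
.apFromFlags <- function(tp, nGT) {
  if (nGT == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  cumTP <- cumsum(tp)
  prec <- cumTP / seq_along(tp)
  rec <- cumTP / nGT
  # interpolate: precision at recall r is the max precision at recall >= r
  pInterp <- rev(cummax(rev(prec)))
  ap <- 0
  prev <- 0
  for (i in seq_along(rec)) {
    if (rec[i] > prev) {
      ap <- ap + (rec[i] - prev) * pInterp[i]
      prev <- rec[i]
    }
  }
  ap
}

#' Mask mAP over IoU thresholds
#'
#' COCO-style mask mean average precision with class-aware greedy
#' matching: per class and threshold, predictions are taken in descending
#' score order and each is matched to the unmatched same-class,
#' same-frame ground-truth mask of highest IoU at or above the threshold.
#' AP uses all-point interpolation of the precision-recall curve; the mAP
#' is the mean over classes present in the ground truth and over the
#' thresholds.
#'
#' @param predictions list of predictions, each a list with fields
#'   \code{mask} (logical matrix), \code{class} (integer), \code{score}
#'   (numeric) and \code{frame} (identifier).
#' @param gts list of ground-truth objects, each with \code{mask},
#'   \code{class} and \code{frame}.
#' @param thresholds IoU thresholds (default 0.50, 0.55, ..., 0.95).
#' @return List with \code{mAP} (scalar) and \code{perClassAP} (named
#'   vector over classes present in the ground truth).
#' @export
maskMAP <- function(predictions, gts,
                    thresholds = seq(0.5, 0.95, by = 0.05)) {
  gtClasses <- vapply(gts, function(g) as.integer(g$class), integer(1L))
  classes <- sort(unique(gtClasses))
  if (!length(classes))
    return(list(mAP = NA_real_, perClassAP = setNames(numeric(0),
                                                      character(0))))
  predClasses <- vapply(predictions, function(p) as.integer(p$class),
                        integer(1L))
  predScores <- vapply(predictions, function(p) as.numeric(p$score),
                       numeric(1L))
  predFrames <- vapply(predictions, function(p) as.character(p$frame),
                       character(1L))
  gtFrames <- vapply(gts, function(g) as.character(g$frame), character(1L))
  perClass <- setNames(numeric(length(classes)), as.character(classes))
  for (cl in classes) {
    pIdx <- which(predClasses == cl)
    pIdx <- pIdx[order(-predScores[pIdx])]
    gIdx <- which(gtClasses == cl)
    # IoU table between this class's predictions and ground truths
    iou <- matrix(0, length(pIdx), length(gIdx))
    if (length(pIdx) && length(gIdx)) {
      for (i in seq_along(pIdx)) for (j in seq_along(gIdx)) {
        if (predFrames[pIdx[i]] == gtFrames[gIdx[j]]) {
          iou[i, j] <- .maskIoU(predictions[[pIdx[i]]]$mask,
                                gts[[gIdx[j]]]$mask)
        }
      }
    }
    aps <- vapply(thresholds, function(thr) {
      matched <- logical(length(gIdx))
      tp <- logical(length(pIdx))
      for (i in seq_along(pIdx)) {
        cand <- which(!matched & iou[i, ] >= thr)
        if (length(cand)) {
          best <- cand[which.max(iou[i, cand])]
          matched[best] <- TRUE
          tp[i] <- TRUE
        }
      }
      .apFromFlags(tp, length(gIdx))
    }, numeric(1L))
    perClass[as.character(cl)] <- mean(aps)
  }
  list(mAP = mean(perClass), perClassAP = perClass)
}

#' Evaluate predictions against labeled scenes
#'
#' Computes the full report: per-frame and dataset type mIoU (painting
#' each instance's class over its mask), part mIoU when predicted part
#' maps are supplied, and mask mAP over 0.50:0.95. Evaluation never
#' filters on clasper visibility: all images and instances count.
#'
#' @param results list of \code{\linkS4class{InstanceResult}} objects.
#' @param scenes list of matching \code{\linkS4class{LabeledScene}}s.
#' @param partPreds optional list of predicted part-label matrices.
#' @param nClasses number of instrument types.
#' @param nParts number of part labels.
#' @return An \code{\linkS4class{EvalReport}}.
#' @export
evaluateScenes <- function(results, scenes, partPreds = NULL, nClasses = 7L,
                           nParts = 4L) {
  stopifnot(length(results) == length(scenes))
  predMaps <- lapply(results, typeLabelMap)
  gtMaps <- lapply(scenes, typeLabelMap)
  perFrame <- mapply(frameMIoU, predMaps, gtMaps,
                     MoreArgs = list(nLabels = nClasses))
  names(perFrame) <- vapply(scenes, frameId, character(1L))
  defined <- perFrame[!is.na(perFrame)]
  typesMIoU <- if (length(defined)) mean(defined) else NA_real_
  partsMIoU <- NA_real_
  if (!is.null(partPreds)) {
    partsMIoU <- datasetMIoU(partPreds, lapply(scenes, partMap),
                             nLabels = nParts)
  }
  preds <- list()
  gts <- list()
  for (i in seq_along(scenes)) {
    fid <- frameId(scenes[[i]])
    res <- results[[i]]
    inst <- instanceMap(res)
    for (j in seq_along(classLabels(res))) {
      preds[[length(preds) + 1L]] <- list(mask = inst == j,
                                          class = classLabels(res)[j],
                                          score = detectionScores(res)[j],
                                          frame = fid)
    }
    ginst <- instanceMap(scenes[[i]])
    tps <- instrumentTypes(scenes[[i]])
    for (key in names(tps)) {
      gts[[length(gts) + 1L]] <- list(mask = ginst == as.integer(key),
                                      class = tps[[key]], frame = fid)
    }
  }
  mm <- maskMAP(preds, gts)
  new("EvalReport", perFrameMIoU = perFrame, typesMIoU = typesMIoU,
      partsMIoU = partsMIoU, mAP5095 = mm$mAP, perClassAP = mm$perClassAP,
      nFrames = length(scenes))
}
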
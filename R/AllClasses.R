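#' @useDynLib CentroidSeg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats median rnorm runif setNames
NULL

# part label codes used throughout: 0 background, 1 shaft, 2 wrist,
# 3 clasper, 4 other
.PART_BACKGROUND <- 0L
.PART_SHAFT <- 1L
.PART_WRIST <- 2L
.PART_CLASPER <- 3L
.PART_OTHER <- 4L

#' Part label names
#'
#' The fixed instrument part vocabulary. Code 0 is background; codes 1--4
#' are the four annotated instrument parts.
#'
#' @return Named integer vector mapping part names to label codes.
#' @export
#' @examples
#' partLabels()
partLabels <- function() {
  c(background = 0L, shaft = 1L, wrist = 2L, clasper = 3L, other = 4L)
}

#' Labeled scene: one frame with instance, part and type annotations
#'
#' A \code{LabeledScene} couples an RGB frame with a per-pixel instance-id
#' map (0 = background, positive integers = instrument instances), a
#' per-pixel part-label map (see \code{\link{partLabels}}), a per-instance
#' type label in \code{1..nClasses}, and a per-instance clasper-visibility
#' flag. The two label maps must agree on which pixels are foreground, and
#' every id present in the instance map must carry a type and a visibility
#' flag; \code{\link{validateScene}} reports violations without raising.
#'
#' Coordinates are image-style: row 1 is the top row, and a pixel is
#' addressed as (row, col).
#'
#' @slot image numeric array, height x width x 3, values in [0, 1].
#' @slot instanceMap integer matrix, height x width.
#' @slot partMap integer matrix, height x width, values in 0..4.
#' @slot types named integer vector keyed by instance id.
#' @slot clasperVisible named logical vector keyed by instance id.
#' @slot frameId character scalar.
#' @export
setClass("LabeledScene",
  slots = c(image = "array", instanceMap = "matrix", partMap = "matrix",
            types = "integer", clasperVisible = "logical",
            frameId = "character"))

setValidity("LabeledScene", function(object) {
  msgs <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3L] != 3L)
    msgs <- c(msgs, "image must be a height x width x 3 array")
  if (!identical(dim(object@instanceMap), d[1:2]))
    msgs <- c(msgs, "instanceMap dimensions must match image")
  if (!identical(dim(object@partMap), d[1:2]))
    msgs <- c(msgs, "partMap dimensions must match image")
  if (length(object@frameId) != 1L)
    msgs <- c(msgs, "frameId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Training targets derived from a labeled scene
#'
#' Holds the dense regression and classification targets used to train the
#' segmentation network: the part-label target, the per-pixel offset field
#' pointing from each foreground pixel to its instance centroid (stored so
#' that pixel - offset = centroid), the centroid heatmap built from
#' unnormalised Gaussians (maximum-combined where instances overlap), the
#' integer centroid of every instance, and the foreground mask.
#'
#' @slot partTarget integer matrix in 0..4.
#' @slot offsetTarget numeric array, height x width x 2 (row, col
#'   components, in pixels); zero outside the foreground.
#' @slot heatmapTarget numeric matrix in [0, 1], exactly 1 at every rounded
#'   centroid pixel.
#' @slot centroidList integer matrix with one (row, col) row per instance,
#'   rownames = instance ids.
#' @slot foregroundMask logical matrix, TRUE where partTarget != 0.
#' @export
setClass("TargetBundle",
  slots = c(partTarget = "matrix", offsetTarget = "array",
            heatmapTarget = "matrix", centroidList = "matrix",
            foregroundMask = "matrix"))

#' Raw network outputs for one frame
#'
#' @slot partLogits numeric array, height x width x (parts + 1).
#' @slot partProbs numeric array, softmax of partLogits over the last axis.
#' @slot offsets numeric array, height x width x 2, unbounded (pixels).
#' @slot heatmap numeric matrix in (0, 1) (sigmoid-activated).
#' @slot fSeg numeric array, height x width x channels: the last feature
#'   map of the segmentation decoder, before the part-logit projection;
#'   this is the feature map the per-instance classifier consumes.
#' @export
setClass("PredictionBundle",
  slots = c(partLogits = "array", partProbs = "array", offsets = "array",
            heatmap = "matrix", fSeg = "array"))

setValidity("PredictionBundle", function(object) {
  d <- dim(object@partLogits)[1:2]
  msgs <- character()
  if (!identical(dim(object@heatmap), d))
    msgs <- c(msgs, "heatmap shape must match partLogits")
  if (!identical(dim(object@offsets)[1:2], d) || dim(object@offsets)[3L] != 2L)
    msgs <- c(msgs, "offsets must be height x width x 2")
  if (!identical(dim(object@fSeg)[1:2], d))
    msgs <- c(msgs, "fSeg shape must match partLogits")
  if (length(msgs)) msgs else TRUE
})

#' Final per-frame instance segmentation and typing result
#'
#' Instance ids are the centroid ranks: id 1 is the highest-scoring
#' centroid. Ids present in \code{instanceMap} index the rows of
#' \code{classProbs} and the entries of \code{classLabel} and
#' \code{detectionScore}.
#'
#' @slot instanceMap integer matrix; 0 = background.
#' @slot centroids numeric matrix with columns row, col, score, ordered by
#'   descending score.
#' @slot classProbs numeric matrix, one row per instance, one column per
#'   instrument type; rows sum to 1.
#' @slot classLabel integer vector, argmax type per instance.
#' @slot detectionScore numeric vector, centroid score times max class
#'   probability.
#' @export
setClass("InstanceResult",
  slots = c(instanceMap = "matrix", centroids = "matrix",
            classProbs = "matrix", classLabel = "integer",
            detectionScore = "numeric"))

setValidity("InstanceResult", function(object) {
  n <- nrow(object@centroids)
  msgs <- character()
  ids <- setdiff(unique(as.integer(object@instanceMap)), 0L)
  if (length(ids) && (min(ids) < 1L || max(ids) > n))
    msgs <- c(msgs, "instance ids must index the centroid list")
  if (n > 0L && nrow(object@classProbs) != n &&
      nrow(object@classProbs) != 0L)  # 0 rows: segmentation-only result
    msgs <- c(msgs, "classProbs must have one row per centroid")
  if (length(msgs)) msgs else TRUE
})

#' Evaluation report for a set of frames
#'
#' @slot perFrameMIoU named numeric vector of per-frame type mIoU values
#'   (NA where no instrument is present in the ground truth).
#' @slot typesMIoU numeric scalar: mean over frames with a present type.
#' @slot partsMIoU numeric scalar: same protocol on part labels.
#' @slot mAP5095 numeric scalar: mask mAP averaged over IoU thresholds
#'   0.50, 0.55, ..., 0.95.
#' @slot perClassAP named numeric vector: per-type AP averaged over
#'   thresholds.
#' @slot nFrames integer.
#' @export
setClass("EvalReport",
  slots = c(perFrameMIoU = "numeric", typesMIoU = "numeric",
            partsMIoU = "numeric", mAP5095 = "numeric",
            perClassAP = "numeric", nFrames = "integer"))

setMethod("show", "LabeledScene", function(object) {
  d <- dim(object@instanceMap)
  k <- length(object@types)
  cat(sprintf("LabeledScene '%s': %d x %d, %d instance%s\n",
              object@frameId, d[1L], d[2L], k, if (k == 1L) "" else "s"))
  if (k) {
    vis <- ifelse(object@clasperVisible[names(object@types)], "visible",
                  "hidden")
    cat(sprintf("  id %s: type %d, clasper %s\n", names(object@types),
                object@types, vis), sep = "")
  }
  invisible(object)
})

setMethod("show", "TargetBundle", function(object) {
  d <- dim(object@partTarget)
  cat(sprintf("TargetBundle: %d x %d, %d centroid(s), %d foreground px\n",
              d[1L], d[2L], nrow(object@centroidList),
              sum(object@foregroundMask)))
  invisible(object)
})

setMethod("show", "PredictionBundle", function(object) {
  d <- dim(object@partLogits)
  cat(sprintf(
    "PredictionBundle: %d x %d, %d part classes, %d f_seg channels\n",
    d[1L], d[2L], d[3L], dim(object@fSeg)[3L]))
  invisible(object)
})

setMethod("show", "InstanceResult", function(object) {
  n <- nrow(object@centroids)
  cat(sprintf("InstanceResult: %d instance%s\n", n, if (n == 1L) "" else "s"))
  if (n) {
    cat(sprintf("  id %d @(%d,%d): class %d, score %.3f\n", seq_len(n),
                as.integer(round(object@centroids[, 1L])),
                as.integer(round(object@centroids[, 2L])),
                object@classLabel, object@detectionScore), sep = "")
  }
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d frames\n", object@nFrames))
  cat(sprintf("  types mIoU: %.4f\n", object@typesMIoU))
  cat(sprintf("  parts mIoU: %.4f\n", object@partsMIoU))
  cat(sprintf("  mask mAP (0.50:0.95): %.4f\n", object@mAP5095))
  invisible(object)
})
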
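# The four training losses and the joint objective. Each loss is a pure
# function of predictions and targets; the training loop differentiates
# them analytically (see pipeline.R), so the definitions here are the
# single source of truth for the forward values the tests pin down.

.asChannelMatrix <- function(x) {
  # H x W x C array (or H x W matrix) -> (H*W) x C matrix, column-major pixels
  if (is.matrix(x)) return(matrix(as.numeric(x), ncol = 1L))
  d <- dim(x)
  matrix(x, d[1L] * d[2L], d[3L])
}

#' Loss configuration
#'
#' Bundles the loss hyperparameters: the focal exponents alpha (on the
#' prediction) and beta (the penalty-reduction exponent on the soft
#' target), the segmentation weight gamma of the joint objective, the DICE
#' smoothing epsilon, the clamping epsilon applied before logarithms, and
#' the per-class weights of the instance-type cross-entropy (normalised to
#' mean 1).
#'
#' @param alpha focal exponent (default 2).
#' @param beta penalty exponent (default 4).
#' @param gamma segmentation weight in the joint loss (default 10).
#' @param diceEpsilon DICE smoothing constant (default 1).
#' @param clampEpsilon probability clamp (default 1e-6).
#' @param classWeights positive numeric vector of per-type weights
#'   (default: all 1 for 7 types); rescaled to mean 1.
#' @return A list with the validated fields.
#' @export
lossConfig <- function(alpha = 2, beta = 4, gamma = 10, diceEpsilon = 1,
                       clampEpsilon = 1e-6, classWeights = rep(1, 7)) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, diceEpsilon > 0,
            clampEpsilon > 0, all(classWeights > 0))
  classWeights <- classWeights / mean(classWeights)
  list(alpha = alpha, beta = beta, gamma = gamma, diceEpsilon = diceEpsilon,
       clampEpsilon = clampEpsilon, classWeights = classWeights)
}

#' Segmentation loss: cross-entropy plus soft DICE
#'
#' The cross-entropy term is the mean over pixels of the negative
#' log-probability of the target part label. The DICE term is soft
#' (computed on probabilities, not argmax), averaged over all part classes
#' including background: 1 - mean_c (2 sum(p_c g_c) + eps) /
#' (sum(p_c) + sum(g_c) + eps), with one-hot targets g.
#'
#' @param partProbs numeric array height x width x (parts + 1) of softmax
#'   probabilities (or an equivalent pixels x classes matrix).
#' @param partTarget integer matrix (or vector) of part labels in
#'   0..parts.
#' @param diceEpsilon DICE smoothing constant (default 1).
#' @param clampEpsilon probability clamp before the log (default 1e-6).
#' @return Scalar loss (cross-entropy + DICE).
#' @export
segLoss <- function(partProbs, partTarget, diceEpsilon = 1,
                    clampEpsilon = 1e-6) {
  P <- if (is.matrix(partProbs) && length(partTarget) == nrow(partProbs))
    partProbs else .asChannelMatrix(partProbs)
  tg <- as.integer(partTarget)
  if (length(tg) != nrow(P)) stop("shape mismatch between probs and target")
  nc <- ncol(P)
  if (any(tg < 0L) || any(tg >= nc)) stop("target label out of range")
  idx <- cbind(seq_along(tg), tg + 1L)
  ce <- -mean(log(pmin(pmax(P[idx], clampEpsilon), 1 - clampEpsilon)))
  dice <- 0
  for (k in seq_len(nc)) {
    g <- as.numeric(tg == k - 1L)
    dice <- dice + (2 * sum(P[, k] * g) + diceEpsilon) /
      (sum(P[, k]) + sum(g) + diceEpsilon)
  }
  ce + (1 - dice / nc)
}

#' Offset loss: masked mean L1
#'
#' Mean over foreground pixels of |d_row| + |d_col| between predicted and
#' target offsets; background pixels are ignored entirely, and a frame
#' with no foreground contributes 0.
#'
#' @param predOffsets,targetOffsets numeric arrays height x width x 2 (or
#'   pixels x 2 matrices).
#' @param foregroundMask logical matrix (or vector) marking foreground.
#' @return Scalar loss.
#' @export
offsetLoss <- function(predOffsets, targetOffsets, foregroundMask) {
  p <- .asChannelMatrix(predOffsets)
  t <- .asChannelMatrix(targetOffsets)
  m <- as.logical(foregroundMask)
  if (nrow(p) != length(m) || nrow(t) != length(m))
    stop("shape mismatch")
  n <- sum(m)
  if (n == 0L) return(0)
  sum(abs(p[m, ] - t[m, ])) / n
}

#' Centroid loss: penalty-reduced pixel-wise focal loss
#'
#' For pixels where the target equals 1 (the exact centroids) the loss is
#' -(1-yhat)^alpha log(yhat); elsewhere it is
#' -(1-y)^beta yhat^alpha log(1-yhat), so negatives close to a true centre
#' (large Gaussian tail y) are down-weighted by the (1-y)^beta penalty
#' factor. The sum is normalised by the number of ground-truth instances
#' (floor 1, so empty frames are defined).
#'
#' @param predHeatmap numeric matrix in (0, 1); values are clamped to
#'   [clampEpsilon, 1 - clampEpsilon] before the logarithms.
#' @param targetHeatmap numeric matrix in [0, 1] (Gaussian target).
#' @param nInstances number of ground-truth instances in the frame.
#' @param alpha focal exponent on the prediction (default 2).
#' @param beta penalty exponent on the soft target (default 4).
#' @param clampEpsilon probability clamp (default 1e-6).
#' @return Scalar loss.
#' @export
centroidLoss <- function(predHeatmap, targetHeatmap, nInstances, alpha = 2,
                         beta = 4, clampEpsilon = 1e-6) {
  if (!identical(dim(predHeatmap), dim(targetHeatmap)))
    stop("shape mismatch")
  y <- as.numeric(targetHeatmap)
  p <- pmin(pmax(as.numeric(predHeatmap), clampEpsilon), 1 - clampEpsilon)
  pos <- y >= 1 - 1e-12
  N <- max(1, nInstances)
  lpos <- (1 - p[pos])^alpha * log(p[pos])
  lneg <- (1 - y[!pos])^beta * p[!pos]^alpha * log(1 - p[!pos])
  -(sum(lpos) + sum(lneg)) / N
}

#' Instance-type loss: weighted cross-entropy
#'
#' Per classified instance, -w_c log(p_c) at the true class c; with
#' several instances the mean over instances is returned. The weights are
#' the inverse type occurrence statistics of the training split,
#' normalised to mean 1 (see \code{\link{classWeightsFromCounts}}).
#'
#' @param classProbs numeric vector of type probabilities, or a matrix
#'   with one row per instance.
#' @param trueClass integer true type(s) in 1..nClasses.
#' @param classWeights positive per-class weights (default all 1).
#' @return Scalar loss.
#' @export
typeLoss <- function(classProbs, trueClass, classWeights = NULL) {
  if (!is.matrix(classProbs)) classProbs <- matrix(classProbs, nrow = 1L)
  trueClass <- as.integer(trueClass)
  if (length(trueClass) != nrow(classProbs))
    stop("one true class per instance required")
  if (any(trueClass < 1L) || any(trueClass > ncol(classProbs)))
    stop("unknown class index")
  if (is.null(classWeights)) classWeights <- rep(1, ncol(classProbs))
  p <- pmax(classProbs[cbind(seq_along(trueClass), trueClass)], 1e-12)
  mean(-classWeights[trueClass] * log(p))
}

#' Inverse-frequency class weights
#'
#' Computes 1/count per class from per-instance type counts of the
#' training split and rescales to mean 1. Classes absent from the split
#' (count 0) are given the largest observed weight before normalisation.
#'
#' @param counts non-negative integer vector of per-type instance counts.
#' @return Numeric weight vector with mean 1.
#' @export
#' @examples
#' classWeightsFromCounts(c(10, 5))  # (2/3, 4/3)
classWeightsFromCounts <- function(counts) {
  stopifnot(all(counts >= 0), any(counts > 0))
  w <- ifelse(counts > 0, 1 / counts, NA_real_)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / mean(w)
}

#' Joint training objective
#'
#' L = L_type + L_offset + L_centroid + gamma * L_seg, with gamma large
#' (default 10) to enforce good segmentation masks.
#'
#' @param typeLoss,offsetLoss,centroidLoss,segLoss scalar component losses.
#' @param gamma segmentation weight (default 10).
#' @return Scalar joint loss.
#' @export
jointLoss <- function(typeLoss, offsetLoss, centroidLoss, segLoss,
                      gamma = 10) {
  stopifnot(is.finite(typeLoss), is.finite(offsetLoss),
            is.finite(centroidLoss), is.finite(segLoss))
  typeLoss + offsetLoss + centroidLoss + gamma * segLoss
}
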
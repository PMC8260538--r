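# From raw predictions to instances: heatmap peak extraction by local
# non-maximum suppression, nearest-centroid pixel grouping, and
# per-instance classification.

#' Inference configuration
#'
#' @param maxCentroids maximum number of extracted centroids (default 4:
#'   at most three instruments plus an ultrasound probe are visible at any
#'   time).
#' @param peakThreshold minimum heatmap value for a peak (default 0.1).
#' @param nmsWindow odd window size of the local-maximum filter
#'   (default 3).
#' @param minInstancePixels instances with fewer assigned pixels are
#'   dropped before classification (default 1).
#' @return A validated configuration list.
#' @export
inferenceConfig <- function(maxCentroids = 4L, peakThreshold = 0.1,
                            nmsWindow = 3L, minInstancePixels = 1L) {
  stopifnot(maxCentroids >= 1L, nmsWindow %% 2L == 1L, peakThreshold >= 0,
            minInstancePixels >= 1L)
  list(maxCentroids = as.integer(maxCentroids),
       peakThreshold = peakThreshold, nmsWindow = as.integer(nmsWindow),
       minInstancePixels = as.integer(minInstancePixels))
}

#' Extract centroid peaks from a heatmap
#'
#' Keeps pixels whose value equals the maximum of their nmsWindow x
#' nmsWindow neighbourhood and exceeds the peak threshold, then returns
#' the top maxCentroids peaks by score, ordered by descending score with
#' ties broken by (row, col) lexicographic order.
#'
#' @param heatmap numeric matrix in [0, 1].
#' @param config an \code{\link{inferenceConfig}}.
#' @return Numeric matrix with columns row, col, score (possibly 0 rows).
#' @export
extractCentroids <- function(heatmap, config = inferenceConfig()) {
  H <- nrow(heatmap)
  W <- ncol(heatmap)
  k <- (config$nmsWindow - 1L) %/% 2L
  locmax <- heatmap
  for (dr in -k:k) for (dc in -k:k) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(-Inf, H, W)
    r1 <- max(1L, 1L + dr); r2 <- min(H, H + dr)
    c1 <- max(1L, 1L + dc); c2 <- min(W, W + dc)
    sh[r1:r2, c1:c2] <- heatmap[(r1:r2) - dr, (c1:c2) - dc]
    locmax <- pmax(locmax, sh)
  }
  isPeak <- heatmap >= locmax & heatmap > config$peakThreshold
  idx <- which(isPeak)
  if (!length(idx)) {
    out <- matrix(numeric(0), 0L, 3L)
    colnames(out) <- c("row", "col", "score")
    return(out)
  }
  pos <- arrayInd(idx, dim(heatmap))
  sc <- heatmap[idx]
  ord <- order(-sc, pos[, 1L], pos[, 2L])
  ord <- ord[seq_len(min(length(ord), config$maxCentroids))]
  out <- cbind(row = pos[ord, 1L], col = pos[ord, 2L], score = sc[ord])
  rownames(out) <- NULL
  out
}

#' Group foreground pixels into instances by nearest centroid
#'
#' Each foreground pixel p is assigned the index (1-based rank in the
#' centroid list) of the centroid closest to its offset-corrected position
#' p - offset(p) in Euclidean distance; ties go to the smallest index.
#' Background pixels get 0. An empty centroid list leaves all pixels at 0
#' and records a warning.
#'
#' @param foregroundMask logical matrix.
#' @param offsets numeric array height x width x 2 (row, col components).
#' @param centroids matrix with columns row, col (and optionally score),
#'   ordered as returned by \code{\link{extractCentroids}}.
#' @return Integer matrix of instance indices.
#' @export
assignInstances <- function(foregroundMask, offsets, centroids) {
  H <- nrow(foregroundMask)
  W <- ncol(foregroundMask)
  out <- matrix(0L, H, W)
  fg <- which(foregroundMask)
  if (!length(fg)) return(out)
  if (is.null(centroids) || nrow(centroids) == 0L) {
    warning("no centroids: all foreground pixels left unassigned")
    return(out)
  }
  pos <- arrayInd(fg, c(H, W))
  pr <- pos[, 1L] - offsets[, , 1L][fg]
  pc <- pos[, 2L] - offsets[, , 2L][fg]
  K <- nrow(centroids)
  D <- matrix(0, length(fg), K)
  for (i in seq_len(K)) {
    D[, i] <- (pr - centroids[i, 1L])^2 + (pc - centroids[i, 2L])^2
  }
  out[fg] <- max.col(-D, ties.method = "first")
  out
}

#' Full per-frame prediction
#'
#' Runs the network, takes the foreground as the pixels whose part argmax
#' is non-background, extracts centroids, groups pixels into instances,
#' drops instances smaller than \code{minInstancePixels} (renumbering
#' compactly while preserving score order), and classifies each surviving
#' instance from the masked feature map fSeg * mask. The detection score
#' of an instance is its centroid score times its maximum class
#' probability. Empty scenes yield a result with zero instances.
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param image numeric array height x width x 3.
#' @param config an \code{\link{inferenceConfig}}.
#' @param prior optional binary presence vector of length nClasses
#'   (required iff the model was built with \code{usePrior}).
#' @return An \code{\linkS4class{InstanceResult}}.
#' @export
predictFrame <- function(model, image, config = inferenceConfig(),
                         prior = NULL) {
  pred <- forwardModel(model, image)
  predictFromBundle(model, pred, config, prior = prior)
}

#' Instance extraction and typing from a prediction bundle
#'
#' The second half of \code{\link{predictFrame}}, split out so that
#' ground-truth bundles or cached predictions can be decoded with the same
#' code path.
#'
#' @param model a model from \code{\link{buildModel}} (used for the
#'   classifier; may be NULL when \code{classify = FALSE}).
#' @param pred a \code{\linkS4class{PredictionBundle}}.
#' @param config an \code{\link{inferenceConfig}}.
#' @param prior optional presence prior.
#' @param classify run the per-instance classifier (default TRUE).
#' @return An \code{\linkS4class{InstanceResult}}.
#' @export
predictFromBundle <- function(model, pred, config = inferenceConfig(),
                              prior = NULL, classify = TRUE) {
  pp <- partProbs(pred)
  d <- dim(pp)
  P1 <- matrix(pp, d[1L] * d[2L], d[3L])
  fg <- matrix(max.col(P1, ties.method = "first") != 1L, d[1L], d[2L])
  cents <- extractCentroids(heatmap(pred), config)
  inst <- if (nrow(cents)) {
    assignInstances(fg, offsetField(pred), cents)
  } else matrix(0L, d[1L], d[2L])
  # drop tiny instances, renumber compactly preserving score order
  sizes <- tabulate(inst[inst > 0L], nbins = nrow(cents))
  keep <- which(sizes >= config$minInstancePixels)
  relab <- matrix(0L, d[1L], d[2L])
  for (j in seq_along(keep)) relab[inst == keep[j]] <- j
  inst <- relab
  cents <- cents[keep, , drop = FALSE]
  n <- nrow(cents)
  nClasses <- if (!is.null(model)) model$config$nClasses else 7L
  probs <- matrix(numeric(0), 0L, nClasses)
  labels <- integer(0)
  scores <- numeric(0)
  if (n > 0L && classify) {
    probs <- matrix(0, n, nClasses)
    for (i in seq_len(n)) {
      probs[i, ] <- classifyInstance(model, fSeg(pred), inst == i,
                                     prior = prior)
    }
    labels <- max.col(probs, ties.method = "first")
    scores <- cents[, "score"] * apply(probs, 1L, max)
  } else if (n > 0L) {
    labels <- rep(NA_integer_, n)
    scores <- cents[, "score"]
  }
  new("InstanceResult", instanceMap = inst, centroids = cents,
      classProbs = probs, classLabel = labels, detectionScore = scores)
}
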
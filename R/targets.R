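# Training-target construction: per-instance integer centroids (the
# per-axis median of the instance pixels), a max-combined Gaussian centroid
# heatmap, and the offset field that lets nearest-centroid grouping undo
# the instance assignment exactly.

# round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer centroid of an instance mask
#'
#' The centroid is the per-axis median of the instance's pixels, rounded
#' half-away-from-zero to an integer pixel. The median of an even-sized
#' list is the mean of the two middle values before rounding. Disconnected
#' visible fragments of one instance (e.g. under occlusion) contribute
#' jointly: the median is taken over all pixels regardless of connectivity.
#'
#' @param pixels integer matrix with two columns (row, col), one row per
#'   pixel; must be non-empty.
#' @return Integer vector c(row, col).
#' @export
#' @examples
#' computeCentroid(rbind(c(0, 0), c(0, 2), c(4, 2)))  # (0, 2)
computeCentroid <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty instance")
  as.integer(.roundHalfAway(c(median(pixels[, 1L]), median(pixels[, 2L]))))
}

#' Gaussian centroid heatmap
#'
#' Places an unnormalised Gaussian bump exp(-d^2 / (2 sigma^2)) at every
#' centroid and combines overlapping bumps with the pixel-wise maximum (not
#' the sum), so the value at each exact centroid pixel is 1. The Gaussian
#' is evaluated densely over the full map, without a truncation radius.
#'
#' @param centroids integer matrix with columns (row, col); zero rows give
#'   an all-zero map.
#' @param shape integer vector c(height, width).
#' @param sigma Gaussian standard deviation in pixels (default 20, the
#'   value used at 512 x 640 training resolution; scale it proportionally
#'   when building targets at other resolutions).
#' @return Numeric height x width matrix in [0, 1].
#' @export
#' @examples
#' hm <- makeHeatmap(rbind(c(5, 5)), c(9, 9), sigma = 2)
#' hm[5, 5]  # exactly 1
makeHeatmap <- function(centroids, shape, sigma = 20) {
  stopifnot(sigma > 0)
  H <- shape[1L]
  W <- shape[2L]
  hm <- matrix(0, H, W)
  if (is.null(centroids) || nrow(centroids) == 0L) return(hm)
  centroids <- as.matrix(centroids)
  if (any(centroids[, 1L] < 1L | centroids[, 1L] > H |
          centroids[, 2L] < 1L | centroids[, 2L] > W))
    stop("centroid out of bounds")
  for (k in seq_len(nrow(centroids))) {
    dr2 <- (seq_len(H) - centroids[k, 1L])^2
    dc2 <- (seq_len(W) - centroids[k, 2L])^2
    g <- exp(-outer(dr2, dc2, "+") / (2 * sigma^2))
    hm <- pmax(hm, g)
  }
  hm
}

#' Offset field pointing pixels at their instance centroid
#'
#' At a foreground pixel p of instance i the stored offset is
#' p - centroid(i), so that p - offset(p) recovers the centroid exactly --
#' the sign convention the nearest-centroid grouping rule requires.
#' Background pixels carry (0, 0).
#'
#' @param instanceMap integer matrix; 0 = background.
#' @param centroidList integer matrix of (row, col) centroids with
#'   rownames = instance ids (as from \code{\link{buildTargets}}).
#' @return Numeric array height x width x 2 (row and col components).
#' @export
makeOffsets <- function(instanceMap, centroidList) {
  H <- nrow(instanceMap)
  W <- ncol(instanceMap)
  off <- array(0, c(H, W, 2L))
  ids <- setdiff(sort(unique(as.integer(instanceMap))), 0L)
  if (!length(ids)) return(off)
  rowIdx <- matrix(seq_len(H), H, W)
  colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)
  o1 <- matrix(0, H, W)
  o2 <- matrix(0, H, W)
  for (id in ids) {
    key <- as.character(id)
    if (!key %in% rownames(centroidList))
      stop("foreground id ", id, " has no centroid")
    m <- instanceMap == id
    o1[m] <- rowIdx[m] - centroidList[key, 1L]
    o2[m] <- colIdx[m] - centroidList[key, 2L]
  }
  off[, , 1L] <- o1
  off[, , 2L] <- o2
  off
}

#' Build all training targets for a scene
#'
#' Composes \code{\link{computeCentroid}}, \code{\link{makeHeatmap}} and
#' \code{\link{makeOffsets}}: the part target is the scene's part map, the
#' foreground mask its non-background support, the heatmap has value 1 at
#' every rounded centroid, and subtracting the offset from any foreground
#' pixel yields its instance's integer centroid exactly.
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param sigma heatmap Gaussian width in pixels (default 20; use a
#'   resolution-proportional value for small scenes, e.g. 2.5 at 64 x 80).
#' @return A \code{\linkS4class{TargetBundle}}.
#' @export
buildTargets <- function(scene, sigma = 20) {
  inst <- instanceMap(scene)
  ids <- setdiff(sort(unique(as.integer(inst))), 0L)
  cents <- matrix(0L, 0L, 2L)
  if (length(ids)) {
    cents <- t(vapply(ids, function(id) {
      computeCentroid(which(inst == id, arr.ind = TRUE))
    }, integer(2L)))
  }
  rownames(cents) <- as.character(ids)
  colnames(cents) <- c("row", "col")
  hm <- makeHeatmap(cents, dim(inst), sigma = sigma)
  off <- makeOffsets(inst, cents)
  new("TargetBundle",
      partTarget = partMap(scene),
      offsetTarget = off,
      heatmapTarget = hm,
      centroidList = cents,
      foregroundMask = partMap(scene) != 0L)
}
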
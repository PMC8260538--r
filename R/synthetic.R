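# Seeded generator of instrument-like scenes.
#
# The generator reproduces the structural premise of endoscopic instrument
# frames that makes type classification hard for pixel-local methods:
# elongated capsule-shaped instruments that enter from the image border at
# arbitrary angles and can span most of the frame, a shaft and wrist whose
# appearance is IDENTICAL across classes, and a small class-specific tip
# (clasper) that is the only discriminative part and may exit the frame.
# Instances may overlap; later draws occlude earlier ones, and an occluded
# instrument keeps a single id across its disconnected visible fragments.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic scene configuration
#'
#' @param height,width scene size in pixels (default 64 x 80, the tiny
#'   training scale; use 256 x 320 for larger scenes).
#' @param nInstruments length-2 integer range for the number of
#'   instruments per scene (default 0 to 4, matching the cap of at most 4
#'   visible objects).
#' @param nClasses number of instrument types (default 7).
#' @param shaftWidth length-2 range of shaft widths in pixels.
#' @param tipStyles character vector mapping class k to a tip template;
#'   one of "prong1", "prong2", "prong3", "prong4", "disc", "ring",
#'   "tbar". Templates must be pairwise distinct.
#' @param overlapAllowed may instruments overlap (default TRUE; later
#'   draws occlude earlier ones).
#' @param backgroundTexture one of "flat", "noise", "blobs".
#' @param minClasperPixels rendered clasper pixels required for the tip to
#'   count as visible (default 10).
#' @return A validated configuration list.
#' @export
synthConfig <- function(height = 64L, width = 80L, nInstruments = c(0L, 4L),
                        nClasses = 7L,
                        shaftWidth = c(5, 7),
                        tipStyles = c("prong1", "prong2", "prong3", "disc",
                                      "ring", "tbar", "prong4")[seq_len(nClasses)],
                        overlapAllowed = TRUE,
                        backgroundTexture = c("noise", "flat", "blobs"),
                        minClasperPixels = 10L) {
  backgroundTexture <- match.arg(backgroundTexture)
  stopifnot(height %% 8 == 0, width %% 8 == 0,
            length(nInstruments) == 2L, nInstruments[2L] <= 4L,
            nInstruments[1L] >= 0L, nClasses >= 2L,
            length(tipStyles) == nClasses,
            !anyDuplicated(tipStyles),
            shaftWidth[1L] >= 2, shaftWidth[2L] >= shaftWidth[1L])
  list(height = as.integer(height), width = as.integer(width),
       nInstruments = as.integer(nInstruments),
       nClasses = as.integer(nClasses), shaftWidth = shaftWidth,
       tipStyles = tipStyles, overlapAllowed = overlapAllowed,
       backgroundTexture = backgroundTexture,
       minClasperPixels = as.integer(minClasperPixels))
}

# distance-field rendering helpers; rr/cc are row/col coordinate matrices
.capsuleMask <- function(rr, cc, a, b, halfw) {
  vr <- b[1L] - a[1L]
  vc <- b[2L] - a[2L]
  len2 <- vr * vr + vc * vc
  if (len2 < 1e-12) {
    d2 <- (rr - a[1L])^2 + (cc - a[2L])^2
    return(d2 <= halfw^2)
  }
  t <- ((rr - a[1L]) * vr + (cc - a[2L]) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (rr - (a[1L] + t * vr))^2 + (cc - (a[2L] + t * vc))^2
  d2 <= halfw^2
}

.discMask <- function(rr, cc, ctr, rad) {
  (rr - ctr[1L])^2 + (cc - ctr[2L])^2 <= rad^2
}

.rotate <- function(d, angleDeg) {
  a <- angleDeg * pi / 180
  c(cos(a) * d[1L] - sin(a) * d[2L], sin(a) * d[1L] + cos(a) * d[2L])
}

# tip templates: masks of the clasper, anchored at `p` pointing along `d`,
# scaled by `s` (a length scale in pixels)
.tipMask <- function(style, rr, cc, p, d, s) {
  q <- c(-d[2L], d[1L])
  prongs <- function(angles, len = 1.7 * s, hw = 0.2 * s) {
    m <- matrix(FALSE, nrow(rr), ncol(rr))
    for (a in angles) {
      da <- .rotate(d, a)
      m <- m | .capsuleMask(rr, cc, p, p + len * da, hw)
    }
    m
  }
  switch(style,
    prong1 = prongs(0, len = 2.0 * s, hw = 0.34 * s),
    prong2 = prongs(c(-38, 38)),
    prong3 = prongs(c(-55, 0, 55), len = 1.5 * s),
    prong4 = prongs(c(-70, -23, 23, 70), len = 1.4 * s, hw = 0.17 * s),
    disc = .discMask(rr, cc, p + 0.8 * s * d, 0.8 * s),
    ring = .discMask(rr, cc, p + 1.0 * s * d, 1.0 * s) &
      !.discMask(rr, cc, p + 1.0 * s * d, 0.55 * s),
    tbar = .capsuleMask(rr, cc, p + 0.4 * s * d - 1.3 * s * q,
                        p + 0.4 * s * d + 1.3 * s * q, 0.24 * s),
    stop("unknown tip style: ", style))
}

# one instrument's geometry and part masks; NULL if nothing is visible.
# The tip is anchored first (usually inside the frame, pointing anywhere)
# and the shaft is extended backwards until it leaves the image, so every
# instrument enters from a border and spans a large image fraction, while
# most tips stay visible. A fraction of tips is deliberately placed
# outside the frame to produce hidden-clasper cases.
.drawInstrument <- function(cfg, rr, cc) {
  H <- cfg$height
  W <- cfg$width
  diag <- sqrt(H^2 + W^2)
  wristLen <- 0.10 * diag
  tipScale <- runif(1, 0.115, 0.15) * diag
  width <- runif(1, cfg$shaftWidth[1L], cfg$shaftWidth[2L])
  if (runif(1) < 0.15) {
    # hidden tip: anchor it beyond a random border
    side <- sample(4L, 1L)
    p2 <- switch(side,
      c(1 - runif(1, 2, 0.2 * diag), runif(1, 1, W)),
      c(H + runif(1, 2, 0.2 * diag), runif(1, 1, W)),
      c(runif(1, 1, H), 1 - runif(1, 2, 0.2 * diag)),
      c(runif(1, 1, H), W + runif(1, 2, 0.2 * diag)))
  } else {
    p2 <- c(runif(1, 0.12 * H, 0.88 * H), runif(1, 0.12 * W, 0.88 * W))
  }
  d <- .rotate(c(1, 0), runif(1, 0, 360))
  # extend the shaft backwards from the wrist until well outside the frame
  p1 <- p2 - wristLen * d
  back <- 0
  repeat {
    back <- back + 0.05 * diag
    p0 <- p1 - back * d
    if (p0[1L] < -width || p0[1L] > H + width ||
        p0[2L] < -width || p0[2L] > W + width) break
    if (back > 2 * diag) break
  }
  p0 <- p1 - (back + runif(1, 0, 0.1 * diag)) * d
  shaft <- .capsuleMask(rr, cc, p0, p1, width / 2)
  wrist <- .capsuleMask(rr, cc, p1, p2, width / 2 * 0.8)
  cls <- sample.int(cfg$nClasses, 1L)
  clasp <- .tipMask(cfg$tipStyles[cls], rr, cc, p2, d, tipScale)
  # parts are disjoint by priority: clasper > wrist > shaft
  wrist <- wrist & !clasp
  shaft <- shaft & !clasp & !wrist
  any_mask <- shaft | wrist | clasp
  if (sum(any_mask) < 30) return(NULL)
  tipCenter <- p2 + 0.8 * tipScale * d
  list(shaft = shaft, wrist = wrist, clasper = clasp, class = cls,
       tipCenter = tipCenter, mask = any_mask)
}

.background <- function(cfg, rr, cc) {
  H <- cfg$height
  W <- cfg$width
  base <- switch(cfg$backgroundTexture,
    flat = matrix(0.25, H, W),
    noise = matrix(0.25 + rnorm(H * W, 0, 0.03), H, W),
    blobs = {
      b <- matrix(0.22, H, W)
      for (i in 1:4) {
        ctr <- c(runif(1, 1, H), runif(1, 1, W))
        amp <- runif(1, -0.08, 0.10)
        s2 <- runif(1, (0.15 * H)^2, (0.4 * H)^2)
        b <- b + amp * exp(-((rr - ctr[1L])^2 + (cc - ctr[2L])^2) / (2 * s2))
      }
      b + matrix(rnorm(H * W, 0, 0.015), H, W)
    })
  pmin(pmax(base, 0), 1)
}

# part colours (RGB), identical for every class and instance by design:
# a pixel-local classifier can name the part but never the instrument type
.PART_COLOURS <- rbind(shaft = c(0.72, 0.72, 0.80),
                       wrist = c(0.86, 0.82, 0.72),
                       clasper = c(0.60, 0.70, 0.60))

#' Generate one synthetic labeled scene
#'
#' Draws K instruments (K uniform in the configured range); each is a
#' capsule-shaped shaft entering from a random border at a random angle, a
#' short wrist, and a class-specific tip. Shaft and wrist appearance is
#' identical across classes, so the type is discriminable only from the
#' tip geometry. Overlaps are resolved by draw order (later instruments
#' occlude earlier ones). Clasper visibility is derived from the rendered
#' result: the tip centre must lie inside the frame and at least
#' \code{minClasperPixels} clasper pixels of the instance must survive
#' occlusion. Fully deterministic given \code{seed}.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A \code{\linkS4class{LabeledScene}} that passes
#'   \code{\link{validateScene}}.
#' @export
#' @examples
#' sc <- generateScene(synthConfig(), seed = 1)
#' validateScene(sc)
generateScene <- function(config = synthConfig(), seed = 1L) {
  .withSeed(seed, .generateSceneImpl(config, seed))
}

.generateSceneImpl <- function(cfg, seed) {
  H <- cfg$height
  W <- cfg$width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  K <- sample(seq.int(cfg$nInstruments[1L], cfg$nInstruments[2L]), 1L)
  img <- array(0, c(H, W, 3L))
  bg <- .background(cfg, rr, cc)
  for (ch in 1:3) img[, , ch] <- bg
  inst <- matrix(0L, H, W)
  part <- matrix(0L, H, W)
  types <- integer(0)
  tipIn <- logical(0)
  drawn <- 0L
  attempts <- 0L
  while (drawn < K && attempts < 100L) {
    attempts <- attempts + 1L
    ins <- .drawInstrument(cfg, rr, cc)
    if (is.null(ins)) next
    if (!cfg$overlapAllowed && any(ins$mask & inst != 0L)) next
    drawn <- drawn + 1L
    inst[ins$mask] <- drawn
    part[ins$shaft] <- .PART_SHAFT
    part[ins$wrist] <- .PART_WRIST
    part[ins$clasper] <- .PART_CLASPER
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[ins$shaft] <- .PART_COLOURS["shaft", ch]
      pl[ins$wrist] <- .PART_COLOURS["wrist", ch]
      pl[ins$clasper] <- .PART_COLOURS["clasper", ch]
      img[, , ch] <- pl
    }
    types <- c(types, ins$class)
    tc <- ins$tipCenter
    tipIn <- c(tipIn, tc[1L] >= 1 && tc[1L] <= H && tc[2L] >= 1 && tc[2L] <= W)
  }
  # occlusion can erase earlier instruments completely; relabel compactly
  keep <- sort(setdiff(unique(as.integer(inst)), 0L))
  relab <- matrix(0L, H, W)
  for (j in seq_along(keep)) relab[inst == keep[j]] <- j
  inst <- relab
  types <- types[keep]
  tipIn <- tipIn[keep]
  # part labels must vanish with the instance map (foreground consistency)
  part[inst == 0L] <- 0L
  img <- img + array(rnorm(length(img), 0, 0.02), dim(img))
  img <- pmin(pmax(img, 0), 1)
  ids <- as.character(seq_along(types))
  scene <- LabeledScene(img, inst, part,
                        types = setNames(types, ids),
                        clasperVisible = setNames(rep(FALSE, length(types)),
                                                  ids),
                        frameId = sprintf("synth%08d", as.integer(seed)))
  counted <- deriveClasperVisibility(scene, cfg$minClasperPixels)
  vis <- counted & setNames(tipIn, ids)[names(counted)]
  scene@clasperVisible <- vis
  scene
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{nFrames} scenes in the manifest format of
#' \code{\link{writeSceneManifest}}, together with per-type instance
#' counts (the occurrence statistics that feed
#' \code{\link{classWeightsFromCounts}}).
#'
#' @param config a \code{\link{synthConfig}}.
#' @param nFrames number of frames.
#' @param seed integer seed; frame i uses a seed derived from it.
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
generateDataset <- function(config = synthConfig(), nFrames, seed, dir) {
  scenes <- generateScenes(config, nFrames, seed)
  counts <- classOccurrenceCounts(scenes, config$nClasses)
  writeSceneManifest(scenes, dir,
                     extra = list(class_counts = as.list(counts),
                                  seed = seed))
}

#' Generate a list of scenes in memory
#'
#' @inheritParams generateDataset
#' @return List of \code{\linkS4class{LabeledScene}} objects; scene i is
#'   \code{generateScene(config, seed * 10000 + i)} truncated to the
#'   32-bit integer range, so disjoint base seeds give disjoint scenes.
#' @export
generateScenes <- function(config = synthConfig(), nFrames, seed) {
  lapply(seq_len(nFrames), function(i) {
    s <- (as.numeric(seed) * 10000 + i) %% 2147483647
    generateScene(config, seed = as.integer(s))
  })
}

#' Per-type instance counts over a set of scenes
#'
#' @param scenes list of \code{\linkS4class{LabeledScene}} objects.
#' @param nClasses number of types.
#' @return Integer vector of length \code{nClasses}.
#' @export
classOccurrenceCounts <- function(scenes, nClasses = 7L) {
  counts <- integer(nClasses)
  for (sc in scenes) {
    for (tp in instrumentTypes(sc)) counts[tp] <- counts[tp] + 1L
  }
  counts
}
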
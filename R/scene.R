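#' Construct a labeled scene
#'
#' @param image numeric array height x width x 3 in [0, 1] (a height x
#'   width matrix is expanded to three identical channels; 8-bit integer
#'   input is rescaled to [0, 1]).
#' @param instanceMap integer matrix; 0 = background, positive integers =
#'   instance ids.
#' @param partMap integer matrix with values in 0..4 (see
#'   \code{\link{partLabels}}).
#' @param types named integer vector (or coercible) mapping instance id to
#'   instrument type in 1..nClasses.
#' @param clasperVisible named logical vector mapping instance id to
#'   whether the clasper (tip) is visible; if missing it is derived with
#'   \code{\link{deriveClasperVisibility}}.
#' @param frameId character scalar identifying the frame.
#' @return A \code{\linkS4class{LabeledScene}}.
#' @seealso \code{\link{validateScene}}, \code{\link{generateScene}}
#' @export
#' @examples
#' inst <- matrix(0L, 8, 8); inst[3:5, 2:7] <- 1L
#' part <- matrix(0L, 8, 8); part[3:5, 2:5] <- 1L; part[3:5, 6:7] <- 3L
#' sc <- LabeledScene(array(0.5, c(8, 8, 3)), inst, part, types = c("1" = 2))
#' validateScene(sc)
LabeledScene <- function(image, instanceMap, partMap, types,
                         clasperVisible = NULL, frameId = "frame") {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (max(image) > 1 + 1e-9) image <- image / 255
  storage.mode(instanceMap) <- "integer"
  storage.mode(partMap) <- "integer"
  types <- setNames(as.integer(types), names(types))
  obj <- new("LabeledScene", image = image, instanceMap = instanceMap,
             partMap = partMap, types = types,
             clasperVisible = logical(0), frameId = as.character(frameId))
  if (is.null(clasperVisible)) {
    clasperVisible <- deriveClasperVisibility(obj)
  }
  obj@clasperVisible <- setNames(as.logical(clasperVisible),
                                 names(clasperVisible))
  obj
}

#' Check the invariants of a labeled scene
#'
#' Verifies that instance and part maps mark the same foreground, that
#' every instance id carries a type and a clasper-visibility entry, and
#' that labels lie in their ranges. Violations are reported, never raised,
#' so invalid scenes can be inspected.
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param nParts number of instrument part labels (default 4).
#' @param nClasses number of instrument types (default 7).
#' @return Character vector of violation messages; empty when the scene is
#'   valid. Each message names the broken invariant and an offending pixel
#'   or id.
#' @export
validateScene <- function(scene, nParts = 4L, nClasses = 7L) {
  v <- character()
  inst <- scene@instanceMap
  part <- scene@partMap
  mism <- which((inst != 0L) != (part != 0L))
  if (length(mism)) {
    p <- arrayInd(mism[1L], dim(inst))
    v <- c(v, sprintf(
      "foreground mismatch: instanceMap and partMap disagree at %d pixel(s), first at (%d,%d)",
      length(mism), p[1L], p[2L]))
  }
  ids <- setdiff(sort(unique(as.integer(inst))), 0L)
  for (id in ids) {
    key <- as.character(id)
    if (!key %in% names(scene@types))
      v <- c(v, sprintf("missing type: instance id %d has no type entry", id))
    if (!key %in% names(scene@clasperVisible))
      v <- c(v, sprintf(
        "missing clasper visibility: instance id %d has no entry", id))
  }
  if (any(inst < 0L))
    v <- c(v, "negative instance id in instanceMap")
  bad <- part < 0L | part > nParts
  if (any(bad)) {
    p <- arrayInd(which(bad)[1L], dim(part))
    v <- c(v, sprintf("part label out of range 0..%d at (%d,%d)", nParts,
                      p[1L], p[2L]))
  }
  tv <- scene@types[names(scene@types) %in% as.character(ids)]
  if (length(tv) && (any(tv < 1L) || any(tv > nClasses)))
    v <- c(v, sprintf("instrument type out of range 1..%d for id %s",
                      nClasses, names(tv)[which(tv < 1L | tv > nClasses)[1L]]))
  v
}

#' Derive clasper visibility from pixel counts
#'
#' An instrument's clasper counts as visible when at least
#' \code{minPixels} of its pixels carry the clasper part label. The
#' training protocol filters the classification task on clasper
#' visibility but needs a concrete criterion; this pixel-count rule is
#' the package's operationalisation and is monotone non-increasing in
#' \code{minPixels}.
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param minPixels minimum number of clasper-labelled pixels (default 10).
#' @return Named logical vector keyed by instance id.
#' @export
deriveClasperVisibility <- function(scene, minPixels = 10L) {
  ids <- setdiff(sort(unique(as.integer(scene@instanceMap))), 0L)
  ids <- sort(unique(c(ids, as.integer(names(scene@types)))))
  vis <- vapply(ids, function(id) {
    sum(scene@instanceMap == id & scene@partMap == .PART_CLASPER) >= minPixels
  }, logical(1L))
  setNames(vis, as.character(ids))
}

# ---- dataset manifest I/O ------------------------------------------------
# One JSON manifest per split lists the frames; per frame: an 8-bit RGB
# image PNG, an instance-map PNG (ids split across two 8-bit channels:
# id = 255*R + G, lossless up to 65535), an 8-bit indexed part-map PNG
# (label = round(255*value) in 0..4), and the per-instance annotations
# inline in the manifest.

.writeInstancePNG <- function(instanceMap, path) {
  hi <- instanceMap %/% 255L
  lo <- instanceMap %% 255L
  arr <- array(0, c(dim(instanceMap), 3L))
  arr[, , 1L] <- hi / 255
  arr[, , 2L] <- lo / 255
  png::writePNG(arr, path)
}

.readInstancePNG <- function(path) {
  arr <- png::readPNG(path)
  m <- round(arr[, , 1L] * 255) * 255L + round(arr[, , 2L] * 255)
  storage.mode(m) <- "integer"
  m
}

.writePartPNG <- function(partMap, path) {
  png::writePNG(partMap / 255, path)
}

.readPartPNG <- function(path) {
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

#' Write one labeled scene to disk
#'
#' @param scene a \code{\linkS4class{LabeledScene}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest entry (a list) describing the written
#'   files, with paths relative to \code{dir}.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- scene@frameId
  imgPath <- file.path(dir, paste0(id, "_image.png"))
  instPath <- file.path(dir, paste0(id, "_instances.png"))
  partPath <- file.path(dir, paste0(id, "_parts.png"))
  png::writePNG(scene@image, imgPath)
  .writeInstancePNG(scene@instanceMap, instPath)
  .writePartPNG(scene@partMap, partPath)
  invisible(list(
    frame_id = id,
    image = basename(imgPath),
    instance_map = basename(instPath),
    part_map = basename(partPath),
    types = as.list(scene@types),
    clasper_visible = as.list(scene@clasperVisible)))
}

#' Read a labeled scene from a manifest entry
#'
#' @param entry one element of a parsed manifest (see
#'   \code{\link{readSceneManifest}}).
#' @param dir directory the manifest paths are relative to.
#' @return A \code{\linkS4class{LabeledScene}}.
#' @export
readScene <- function(entry, dir) {
  img <- png::readPNG(file.path(dir, entry$image))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  types <- unlist(entry$types)
  vis <- unlist(entry$clasper_visible)
  LabeledScene(img,
               .readInstancePNG(file.path(dir, entry$instance_map)),
               .readPartPNG(file.path(dir, entry$part_map)),
               types = setNames(as.integer(types), names(types)),
               clasperVisible = setNames(as.logical(vis), names(vis)),
               frameId = entry$frame_id)
}

#' Read a dataset manifest
#'
#' @param path path to a \code{manifest.json} written by
#'   \code{\link{generateDataset}} or \code{\link{writeSceneManifest}}.
#' @param load if TRUE (default) return the scenes; otherwise the parsed
#'   manifest list.
#' @return A list of \code{\linkS4class{LabeledScene}} objects (or the raw
#'   manifest).
#' @export
readSceneManifest <- function(path, load = TRUE) {
  man <- jsonlite::read_json(path)
  if (!load) return(man)
  dir <- dirname(path)
  lapply(man$frames, readScene, dir = dir)
}

#' Write a dataset manifest
#'
#' @param scenes list of \code{\linkS4class{LabeledScene}} objects.
#' @param dir output directory.
#' @param extra named list merged into the top level of the manifest
#'   (e.g. class occurrence counts).
#' @return The manifest path, invisibly.
#' @export
writeSceneManifest <- function(scenes, dir, extra = list()) {
  entries <- lapply(scenes, writeScene, dir = dir)
  man <- c(list(n_frames = length(scenes), frames = entries), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
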
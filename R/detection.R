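# Seed/ant detection: modal background, difference + darkness segmentation,
# 2-of-3 temporal persistence, blob detection and size-gated classification.

#' Build a modal-RGB background model
#'
#' For each pixel the most represented RGB triplet across the supplied frames
#' is retained; ties are broken towards the lexicographically smallest
#' triplet (deterministic). Optional manual patches overwrite rectangular
#' regions, mimicking the manual removal of residual artefacts.
#'
#' @param frames list of >= 2 [ArenaFrame-class] objects with identical
#'   dimensions.
#' @param manualPatches optional list of patches, each a list with `region =
#'   c(x0, y0, x1, y1)` (0-based, inclusive) and `rgb = c(r, g, b)`.
#' @return a [BackgroundModel-class].
#' @export
buildBackground <- function(frames, manualPatches = NULL) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  dims <- lapply(frames, function(f) dim(pixels(f)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("frames have mismatched dimensions")
  H <- dims[[1]][1]; W <- dims[[1]][2]
  npix <- H * W
  nf <- length(frames)
  enc <- matrix(0, npix, nf)
  for (i in seq_len(nf)) {
    px <- round(pixels(frames[[i]]))
    enc[, i] <- as.vector(px[, , 1]) * 65536 + as.vector(px[, , 2]) * 256 +
      as.vector(px[, , 3])
  }
  dt <- data.table::data.table(pix = rep(seq_len(npix), nf),
                               val = as.vector(enc))
  cnt <- dt[, list(n = .N), by = c("pix", "val")]
  data.table::setorderv(cnt, c("pix", "n", "val"), order = c(1L, -1L, 1L))
  mode <- cnt[!duplicated(cnt$pix)]
  data.table::setorder(mode, pix)
  v <- mode$val
  bg <- array(0, dim = c(H, W, 3L))
  bg[, , 1] <- matrix(v %/% 65536, H, W)
  bg[, , 2] <- matrix((v %/% 256) %% 256, H, W)
  bg[, , 3] <- matrix(v %% 256, H, W)
  if (!is.null(manualPatches)) {
    for (p in manualPatches) {
      r <- p$region
      ys <- (r[2]:r[4]) + 1L; xs <- (r[1]:r[3]) + 1L
      for (ch in 1:3) bg[ys, xs, ch] <- p$rgb[ch]
    }
  }
  new("BackgroundModel", pixels = bg, nFramesUsed = as.integer(nf))
}

#' Difference segmentation against the background
#'
#' Flags pixels whose Euclidean RGB distance to the background model strictly
#' exceeds `diffThreshold`.
#'
#' @param frame an [ArenaFrame-class].
#' @param bg a [BackgroundModel-class] of the same dimensions.
#' @param params a [segmentationParams()].
#' @return logical H x W mask.
#' @export
segmentDifference <- function(frame, bg, params = segmentationParams()) {
  px <- pixels(frame); bp <- pixels(bg)
  if (!all(dim(px) == dim(bp))) stop("frame and background dimensions differ")
  d2 <- (px[, , 1] - bp[, , 1])^2 + (px[, , 2] - bp[, , 2])^2 +
    (px[, , 3] - bp[, , 3])^2
  d2 > params@diffThreshold^2
}

#' Darkness segmentation
#'
#' Restricts a mask to pixels whose luminance is at most `darkThreshold`.
#'
#' @inheritParams segmentDifference
#' @param mask logical H x W mask (e.g. from [segmentDifference()]).
#' @return logical H x W mask.
#' @export
segmentDark <- function(frame, mask, params = segmentationParams()) {
  px <- pixels(frame)
  if (!all(dim(px)[1:2] == dim(mask))) stop("mask and frame dimensions differ")
  mask & (luminance(px) <= params@darkThreshold)
}

#' Two-of-three temporal persistence filter
#'
#' Retains pixels present in at least two out of three consecutive masks;
#' the output is aligned with the middle frame.
#'
#' @param masks list of exactly 3 logical masks, ordered by time.
#' @return logical mask.
#' @export
persistenceFilter <- function(masks) {
  if (length(masks) != 3L) stop("need exactly 3 consecutive masks")
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1))))
    stop("masks have mismatched dimensions")
  (masks[[1]] + masks[[2]] + masks[[3]]) >= 2
}

#' Detect blobs in a binary mask
#'
#' Maximal connected components under the configured connectivity, with
#' pixel count and arithmetic-mean centroid (0-based pixel coordinates).
#'
#' @param mask logical matrix.
#' @param params a [segmentationParams()] (controls connectivity).
#' @return data.frame with columns `label`, `size_px`, `x_px`, `y_px`.
#' @export
detectBlobs <- function(mask, params = segmentationParams()) {
  .blobsFromLabels(labelComponents(mask, params@connectivity))
}

#' Convert pixel coordinates to arena centimetres
#'
#' `cm = (px - nestCentre) * resolution / 10`, with the y axis negated so
#' that arena y points up while image y points down.
#'
#' @param pts length-2 vector or n x 2 matrix of 0-based pixel coordinates.
#' @param resolution mm per pixel (> 0).
#' @param nestCentre nest centre in 0-based pixel coordinates.
#' @return coordinates in cm, same shape.
#' @examples
#' pxToCm(c(100, 0), 0.677, c(0, 0))  # (6.77, 0)
#' @export
pxToCm <- function(pts, resolution, nestCentre) {
  stopifnot(resolution > 0)
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L, 2L) else as.matrix(pts)
  out <- cbind((p[, 1] - nestCentre[1]) * resolution / 10,
               -(p[, 2] - nestCentre[2]) * resolution / 10)
  if (vec) as.numeric(out) else out
}

#' @rdname pxToCm
#' @export
cmToPx <- function(pts, resolution, nestCentre) {
  stopifnot(resolution > 0)
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L, 2L) else as.matrix(pts)
  out <- cbind(p[, 1] * 10 / resolution + nestCentre[1],
               -p[, 2] * 10 / resolution + nestCentre[2])
  if (vec) as.numeric(out) else out
}

.emptyBlobDf <- function() {
  data.frame(x_px = numeric(), y_px = numeric(), size_px = integer(),
             x_cm = numeric(), y_cm = numeric())
}

.blobTable <- function(blobs, resolution, nestCentre) {
  if (nrow(blobs) == 0L) return(.emptyBlobDf())
  cm <- pxToCm(cbind(blobs$x_px, blobs$y_px), resolution, nestCentre)
  data.frame(x_px = blobs$x_px, y_px = blobs$y_px, size_px = blobs$size_px,
             x_cm = cm[, 1], y_cm = cm[, 2])
}

#' Classify a frame's blobs into seeds and ants
#'
#' Persistent blobs whose size lies within the seed gate
#' (`seedMinPx..seedMaxPx`, inclusive) are seeds; persistent blobs outside
#' the gate are discarded as static ants or stains. Blobs of the moving
#' (non-persistent) mask are ants, with no size threshold. Centroids are
#' also reported in arena centimetres relative to the nest centre.
#'
#' @param persistent logical mask after the persistence filter.
#' @param moving logical mask of segmented pixels of the current frame; its
#'   non-persistent part is taken as moving pixels.
#' @param params a [segmentationParams()].
#' @param resolution mm per pixel.
#' @param nestCentre nest centre, 0-based pixel coordinates.
#' @param frameIndex,timestamp frame metadata.
#' @return a [FrameDetections-class].
#' @export
classifyFrame <- function(persistent, moving, params = segmentationParams(),
                          resolution = 0.677,
                          nestCentre = c(0, 0), frameIndex = 0L,
                          timestamp = 0) {
  pb <- detectBlobs(persistent, params)
  isSeed <- pb$size_px >= params@seedMinPx & pb$size_px <= params@seedMaxPx
  antMask <- moving & !persistent
  ab <- detectBlobs(antMask, params)
  new("FrameDetections",
      frameIndex = as.integer(frameIndex), timestamp = timestamp,
      seeds = .blobTable(pb[isSeed, , drop = FALSE], resolution, nestCentre),
      ants = .blobTable(ab, resolution, nestCentre),
      discarded = .blobTable(pb[!isSeed, , drop = FALSE], resolution,
                             nestCentre))
}

#' Run the full detection pipeline over a frame sequence
#'
#' For each interior frame t, segmentation masks of frames (t - 1, t, t + 1)
#' are combined by the persistence filter and the frame is classified with
#' [classifyFrame()]. The first and last frames of the sequence receive no
#' seed detections (their persistence window is incomplete); their ants are
#' still detected from their own segmented mask.
#'
#' @param frames list of [ArenaFrame-class], in temporal order.
#' @param bg a [BackgroundModel-class].
#' @param params a [segmentationParams()].
#' @param nestCentre nest centre, 0-based pixel coordinates.
#' @param verbose emit a message about the edge frames.
#' @return list of [FrameDetections-class], one per frame.
#' @export
detectSequence <- function(frames, bg, params = segmentationParams(),
                           nestCentre = NULL, verbose = FALSE) {
  n <- length(frames)
  if (n < 3L) stop("need at least 3 frames for the persistence filter")
  if (is.null(nestCentre)) {
    d <- dim(pixels(frames[[1]]))
    nestCentre <- c((d[2] - 1) / 2, (d[1] - 1) / 2)
  }
  res <- resolution(frames[[1]])
  masks <- lapply(frames, function(f)
    segmentDark(f, segmentDifference(f, bg, params), params))
  if (verbose)
    message("first and last frames get no seed detections ",
            "(incomplete persistence window)")
  out <- vector("list", n)
  for (t in seq_len(n)) {
    if (t == 1L || t == n) {
      persistent <- matrix(FALSE, nrow(masks[[t]]), ncol(masks[[t]]))
    } else {
      persistent <- persistenceFilter(masks[(t - 1L):(t + 1L)])
    }
    out[[t]] <- classifyFrame(persistent, masks[[t]], params, res,
                              nestCentre, frameIndex = t,
                              timestamp = timestamp(frames[[t]]))
  }
  out
}

#' Write / read a detections table
#'
#' Flat CSV with columns `frame_index`, `timestamp_min`, `class`, `x_px`,
#' `y_px`, `x_cm`, `y_cm`, `size_px`.
#'
#' @param detections list of [FrameDetections-class].
#' @param path CSV file path.
#' @return `detectionsToTable` and `readDetectionsCSV` return the flat
#'   data.frame; `writeDetectionsCSV` returns `path` invisibly.
#' @export
detectionsToTable <- function(detections) {
  rows <- lapply(detections, function(fd) {
    mk <- function(df, cls) {
      if (nrow(df) == 0L) return(NULL)
      data.frame(frame_index = fd@frameIndex, timestamp_min = fd@timestamp,
                 class = cls, x_px = df$x_px, y_px = df$y_px,
                 x_cm = df$x_cm, y_cm = df$y_cm, size_px = df$size_px)
    }
    rbind(mk(fd@seeds, "seed"), mk(fd@ants, "ant"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame_index = integer(), timestamp_min = numeric(),
                      class = character(), x_px = numeric(), y_px = numeric(),
                      x_cm = numeric(), y_cm = numeric(), size_px = integer())
  out
}

#' @rdname detectionsToTable
#' @export
writeDetectionsCSV <- function(detections, path) {
  utils::write.csv(detectionsToTable(detections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname detectionsToTable
#' @export
readDetectionsCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
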
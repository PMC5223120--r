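# Constructors, accessors and show methods for the core containers.

#' Create an ArenaFrame
#'
#' @param pixels H x W x 3 numeric array in [0, 255], or an H x W matrix
#'   (replicated to three identical channels).
#' @param resolution mm per pixel.
#' @param timestamp minutes since experiment start.
#' @param cameraId camera label.
#' @return An [ArenaFrame-class] object.
#' @examples
#' f <- arenaFrame(array(200, dim = c(10, 12, 3)))
#' dim(pixels(f))
#' @export
arenaFrame <- function(pixels, resolution = 0.677, timestamp = 0,
                       cameraId = "cam") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  new("ArenaFrame", pixels = pixels, resolution = resolution,
      timestamp = timestamp, cameraId = cameraId)
}

#' @rdname ArenaFrame-class
#' @aliases pixels,ArenaFrame-method
setMethod("pixels", "ArenaFrame", function(object) object@pixels)
#' @rdname ArenaFrame-class
setMethod("resolution", "ArenaFrame", function(object) object@resolution)
#' @rdname ArenaFrame-class
setMethod("timestamp", "ArenaFrame", function(object) object@timestamp)
#' @rdname ArenaFrame-class
setMethod("cameraId", "ArenaFrame", function(object) object@cameraId)

setMethod("show", "ArenaFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "ArenaFrame: %d x %d px, %.3f mm/px, t = %g min, camera '%s'\n",
    d[2], d[1], object@resolution, object@timestamp, object@cameraId))
})

#' @rdname BackgroundModel-class
#' @param object a BackgroundModel.
setMethod("pixels", "BackgroundModel", function(object) object@pixels)

setMethod("show", "BackgroundModel", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BackgroundModel: %d x %d px, modal RGB over %d frames\n",
              d[2], d[1], object@nFramesUsed))
})

#' Segmentation parameter set
#'
#' Defaults follow the package's dark-seeds-on-light-floor conventions:
#' a changed pixel differs from the background by more than 40 grey levels in
#' Euclidean RGB distance and is dark when its luminance is at most 90; seed
#' blobs occupy 5 to 19 pixels (1 to 2.5 mm wide seeds at 0.677 mm/pixel).
#'
#' @param diffThreshold RGB Euclidean difference threshold (grey levels).
#' @param darkThreshold maximum luminance for a dark pixel.
#' @param seedMinPx,seedMaxPx inclusive seed blob-size gate in pixels.
#' @param connectivity 4 or 8.
#' @return A [SegmentationParams-class] object.
#' @examples
#' segmentationParams(diffThreshold = 30)
#' @export
segmentationParams <- function(diffThreshold = 40, darkThreshold = 90,
                               seedMinPx = 5L, seedMaxPx = 19L,
                               connectivity = 8L) {
  new("SegmentationParams", diffThreshold = diffThreshold,
      darkThreshold = darkThreshold, seedMinPx = as.integer(seedMinPx),
      seedMaxPx = as.integer(seedMaxPx),
      connectivity = as.integer(connectivity))
}

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf(paste0(
    "SegmentationParams: diff > %g, dark <= %g, seed size [%d, %d] px, ",
    "%d-connectivity\n"),
    object@diffThreshold, object@darkThreshold, object@seedMinPx,
    object@seedMaxPx, object@connectivity))
})

#' @rdname FrameDetections-class
#' @aliases seeds,FrameDetections-method
#' @param object a FrameDetections.
setMethod("seeds", "FrameDetections", function(object) object@seeds)
#' @rdname FrameDetections-class
setMethod("ants", "FrameDetections", function(object) object@ants)

setMethod("show", "FrameDetections", function(object) {
  cat(sprintf(
    "FrameDetections: frame %d (t = %g min): %d seed(s), %d ant(s), %d discarded\n",
    object@frameIndex, object@timestamp, nrow(object@seeds),
    nrow(object@ants), nrow(object@discarded)))
})

#' Observation regions
#'
#' `discRegion` and `polygonRegion` build the observation windows used by
#' [pointPattern()]. `regionContains` tests point membership, `regionArea`
#' gives the window area and `regionDiameter` the maximal chord, all in the
#' region's units (cm in this package).
#'
#' @param centre disc centre, length-2 numeric.
#' @param radius disc radius.
#' @return A region list (`type`, plus geometry fields).
#' @examples
#' r <- discRegion(c(0, 0), 195)
#' regionArea(r)
#' @export
discRegion <- function(centre = c(0, 0), radius) {
  stopifnot(length(centre) == 2L, radius > 0)
  list(type = "disc", centre = as.numeric(centre), radius = as.numeric(radius))
}

#' @rdname discRegion
#' @param vertices n x 2 matrix of polygon vertices (closed implicitly).
#' @export
polygonRegion <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  list(type = "polygon", vertices = vertices)
}

#' @rdname discRegion
#' @param region a region list.
#' @param pts m x 2 matrix of points.
#' @param tol boundary tolerance.
#' @export
regionContains <- function(region, pts, tol = 0) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  if (region$type == "disc") {
    d2 <- (pts[, 1] - region$centre[1])^2 + (pts[, 2] - region$centre[2])^2
    d2 <= (region$radius + tol)^2
  } else {
    .pointInPolygon(pts, region$vertices)
  }
}

#' @rdname discRegion
#' @export
regionArea <- function(region) {
  if (region$type == "disc") return(pi * region$radius^2)
  v <- region$vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' @rdname discRegion
#' @export
regionDiameter <- function(region) {
  if (region$type == "disc") return(2 * region$radius)
  v <- region$vertices
  max(stats::dist(v))
}

#' Create a PointPattern
#'
#' @param coords n x 2 matrix or data.frame of point coordinates (cm).
#' @param region observation region from [discRegion()] or [polygonRegion()].
#' @return A [PointPattern-class] object.
#' @examples
#' p <- pointPattern(cbind(c(0, 10), c(0, 0)), discRegion(c(0, 0), 50))
#' nPoints(p)
#' @export
pointPattern <- function(coords, region) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(), 0L, 2L)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  new("PointPattern", coords = coords, region = region)
}

#' @rdname PointPattern-class
#' @aliases coords,PointPattern-method
#' @param object a PointPattern.
setMethod("coords", "PointPattern", function(object) object@coords)
#' @rdname PointPattern-class
setMethod("region", "PointPattern", function(object) object@region)
#' @rdname PointPattern-class
setMethod("nPoints", "PointPattern", function(object) nrow(object@coords))

setMethod("show", "PointPattern", function(object) {
  reg <- object@region
  desc <- if (reg$type == "disc")
    sprintf("disc centre (%g, %g), radius %g", reg$centre[1], reg$centre[2],
            reg$radius)
  else sprintf("polygon with %d vertices", nrow(reg$vertices))
  cat(sprintf("PointPattern: %d points in %s\n", nrow(object@coords), desc))
})

setMethod("show", "EnvelopeResult", function(object) {
  cat(sprintf(
    "EnvelopeResult: G-function envelope, %d simulations, %d grid points\n",
    object@nSim, length(object@dGrid)))
})

setMethod("show", "DCLFResult", function(object) {
  cat(sprintf(
    "DCLF test (%s): U = %.4g, rank = %d, p = %.4g -> %s\n",
    object@alternative, object@uObs, object@rank, object@p, object@verdict))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth: %d seed(s), %d ant(s), arena radius %g cm, %.3f mm/px\n",
    nrow(object@seeds), nrow(object@ants), object@arenaRadiusCm,
    object@resolution))
})

#' Create a PlatformROI
#'
#' @param polygon n x 2 matrix of pixel coordinates delimiting the platform.
#' @param gate 2 x 2 matrix: start and end of the directed gate segment.
#'   A trajectory crossing from the negative to the positive side of the
#'   directed gate line counts as entering.
#' @return A [PlatformROI-class] object.
#' @export
platformROI <- function(polygon, gate) {
  new("PlatformROI", polygon = as.matrix(polygon), gate = as.matrix(gate))
}

setMethod("show", "PlatformROI", function(object) {
  cat(sprintf("PlatformROI: polygon with %d vertices, gate (%g,%g)->(%g,%g)\n",
              nrow(object@polygon), object@gate[1, 1], object@gate[1, 2],
              object@gate[2, 1], object@gate[2, 2]))
})
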
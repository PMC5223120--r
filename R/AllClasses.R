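#' @import methods
NULL

#' ArenaFrame: an RGB arena image with physical metadata
#'
#' Container for a single captured (or rendered) arena image. Pixels are kept
#' as an H x W x 3 numeric array of 8-bit channel values (0-255). Pixel
#' coordinates throughout the package are 0-based, x rightward (columns),
#' y downward (rows), so pixel (x, y) lives at `pixels(f)[y + 1, x + 1, ]`.
#'
#' @slot pixels numeric array, H x W x 3, values in [0, 255].
#' @slot resolution physical resolution in mm per pixel (> 0).
#' @slot timestamp acquisition time in minutes since experiment start.
#' @slot cameraId camera label.
#'
#' @exportClass ArenaFrame
setClass("ArenaFrame",
  representation(
    pixels = "array",
    resolution = "numeric",
    timestamp = "numeric",
    cameraId = "character"
  ),
  prototype(resolution = 0.677, timestamp = 0, cameraId = "cam")
)

setValidity("ArenaFrame", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("image must have at least one row and one column")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    return("resolution (mm/pixel) must be a single positive number")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 255)
    return("channel values must lie in [0, 255]")
  TRUE
})

#' SegmentationParams: thresholds for seed/ant segmentation
#'
#' @slot diffThreshold Euclidean RGB distance to the background above which a
#'   pixel is flagged as changed (strict inequality), in grey levels.
#' @slot darkThreshold maximum luminance (mean of R, G, B) for a pixel to count
#'   as "dark".
#' @slot seedMinPx,seedMaxPx inclusive blob-size gate (pixels) for seeds.
#' @slot connectivity pixel connectivity for blob detection, 4 or 8.
#'
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(
    diffThreshold = "numeric",
    darkThreshold = "numeric",
    seedMinPx = "integer",
    seedMaxPx = "integer",
    connectivity = "integer"
  ),
  prototype(diffThreshold = 40, darkThreshold = 90, seedMinPx = 5L,
            seedMaxPx = 19L, connectivity = 8L)
)

setValidity("SegmentationParams", function(object) {
  if (object@diffThreshold <= 0 || object@diffThreshold >= sqrt(3) * 255)
    return("diffThreshold must be in (0, 441.7)")
  if (object@darkThreshold < 0 || object@darkThreshold > 255)
    return("darkThreshold must be in [0, 255]")
  if (object@seedMinPx <= 0L || object@seedMinPx > object@seedMaxPx)
    return("need 0 < seedMinPx <= seedMaxPx")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' BackgroundModel: modal-RGB static background
#'
#' @slot pixels numeric array, H x W x 3; per-pixel modal RGB triplet.
#' @slot nFramesUsed number of frames the model was built from (>= 2).
#'
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(pixels = "array", nFramesUsed = "integer")
)

setValidity("BackgroundModel", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (object@nFramesUsed < 2L)
    return("background must be built from at least 2 frames")
  TRUE
})

#' FrameDetections: classified blobs of one frame
#'
#' Each blob table has columns `x_px`, `y_px` (0-based centroid),
#' `size_px`, `x_cm`, `y_cm` (arena coordinates relative to the nest centre,
#' y pointing up).
#'
#' @slot frameIndex index of the frame within its sequence.
#' @slot timestamp minutes since experiment start.
#' @slot seeds data.frame of blobs classified as seeds.
#' @slot ants data.frame of blobs classified as ants.
#' @slot discarded data.frame of persistent blobs outside the seed size gate
#'   (static ants / stains).
#'
#' @exportClass FrameDetections
setClass("FrameDetections",
  representation(
    frameIndex = "integer",
    timestamp = "numeric",
    seeds = "data.frame",
    ants = "data.frame",
    discarded = "data.frame"
  )
)

.blobCols <- c("x_px", "y_px", "size_px", "x_cm", "y_cm")

setValidity("FrameDetections", function(object) {
  for (nm in c("seeds", "ants", "discarded")) {
    df <- slot(object, nm)
    if (!all(.blobCols %in% names(df)))
      return(sprintf("%s table must have columns %s", nm,
                     paste(.blobCols, collapse = ", ")))
  }
  TRUE
})

#' PointPattern: a planar point pattern with an observation region
#'
#' @slot coords n x 2 numeric matrix of point coordinates (cm), columns x, y.
#' @slot region observation window: a list with `type = "disc"` (fields
#'   `centre`, `radius`) or `type = "polygon"` (field `vertices`, an n x 2
#'   matrix).
#'
#' @exportClass PointPattern
setClass("PointPattern",
  representation(coords = "matrix", region = "list")
)

setValidity("PointPattern", function(object) {
  if (ncol(object@coords) != 2L)
    return("coords must be an n x 2 matrix")
  reg <- object@region
  if (is.null(reg$type) || !reg$type %in% c("disc", "polygon"))
    return("region$type must be 'disc' or 'polygon'")
  if (reg$type == "disc" &&
      (length(reg$centre) != 2L || !is.numeric(reg$radius) || reg$radius <= 0))
    return("disc region needs centre (length 2) and radius > 0")
  if (reg$type == "polygon" &&
      (!is.matrix(reg$vertices) || nrow(reg$vertices) < 3L))
    return("polygon region needs >= 3 vertices")
  if (nrow(object@coords) > 0 &&
      !all(regionContains(reg, object@coords, tol = 1e-7)))
    return("all points must lie inside the region")
  TRUE
})

#' EnvelopeResult: Monte-Carlo CSR envelope of the G-function
#'
#' @slot dGrid increasing distance grid (cm).
#' @slot obs observed G-curve on the grid.
#' @slot simMean pointwise mean of the simulated curves.
#' @slot lo,hi pointwise envelope bounds (min/max over simulations).
#' @slot simCurves nSim x length(dGrid) matrix of simulated G-curves.
#' @slot obsNN observed nearest-neighbour distances.
#' @slot simNN list of per-simulation nearest-neighbour distance vectors.
#' @slot nSim number of simulations.
#'
#' @exportClass EnvelopeResult
setClass("EnvelopeResult",
  representation(
    dGrid = "numeric", obs = "numeric", simMean = "numeric",
    lo = "numeric", hi = "numeric", simCurves = "matrix",
    obsNN = "numeric", simNN = "list", nSim = "integer"
  )
)

setValidity("EnvelopeResult", function(object) {
  k <- length(object@dGrid)
  if (length(object@obs) != k || length(object@lo) != k ||
      length(object@hi) != k || length(object@simMean) != k)
    return("curve lengths must match dGrid")
  if (any(object@lo > object@simMean + 1e-12) ||
      any(object@simMean > object@hi + 1e-12))
    return("need lo <= simMean <= hi pointwise")
  if (object@nSim < 1L) return("nSim must be >= 1")
  TRUE
})

#' DCLFResult: Diggle-Cressie-Loosmore-Ford goodness-of-fit result
#'
#' @slot uObs observed integrated squared deviation.
#' @slot uSim per-simulation statistics (each against the mean of the others).
#' @slot rank 1 + number of simulated statistics exceeding the observed one.
#' @slot p Monte-Carlo p-value, rank / (nSim + 1).
#' @slot verdict one of "clustered", "CSR", "regular".
#' @slot alternative deviation direction tested.
#' @slot dMax upper integration limit (cm).
#'
#' @exportClass DCLFResult
setClass("DCLFResult",
  representation(
    uObs = "numeric", uSim = "numeric", rank = "integer", p = "numeric",
    verdict = "character", alternative = "character", dMax = "numeric"
  )
)

setValidity("DCLFResult", function(object) {
  if (object@p <= 0 || object@p > 1) return("p must be in (0, 1]")
  if (!object@verdict %in% c("clustered", "CSR", "regular"))
    return("verdict must be clustered, CSR or regular")
  TRUE
})

#' SceneTruth: ground truth for synthetic arena scenes
#'
#' @slot seeds data.frame with columns `x_cm`, `y_cm`, `width_mm`,
#'   `appear`, `disappear` (frame indices, inclusive).
#' @slot ants data.frame with columns `x_cm`, `y_cm`, `length_mm`, `heading`
#'   (initial ant states).
#' @slot arenaRadiusCm arena disc radius (cm); nest at the centre.
#' @slot resolution mm per pixel.
#' @slot noiseSigma Gaussian pixel-noise standard deviation (grey levels).
#' @slot cameraOffsets per-camera luminance offsets (grey levels), length 2.
#' @slot floorLevel,seedLevel mean floor and object luminance (grey levels).
#' @slot seed RNG seed controlling rendering noise and ant motion.
#'
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(
    seeds = "data.frame", ants = "data.frame",
    arenaRadiusCm = "numeric", resolution = "numeric",
    noiseSigma = "numeric", cameraOffsets = "numeric",
    floorLevel = "numeric", seedLevel = "numeric", seed = "integer"
  ),
  prototype(resolution = 0.677, noiseSigma = 5, cameraOffsets = c(10, -10),
            floorLevel = 200, seedLevel = 30, seed = 0L)
)

setValidity("SceneTruth", function(object) {
  s <- object@seeds
  if (nrow(s) > 0) {
    if (any(s$width_mm < 1 - 1e-9 | s$width_mm > 2.5 + 1e-9))
      return("seed widths must lie in [1, 2.5] mm")
    if (any(sqrt(s$x_cm^2 + s$y_cm^2) > object@arenaRadiusCm))
      return("all seeds must lie inside the arena")
  }
  a <- object@ants
  if (nrow(a) > 0) {
    if (any(a$length_mm < 4 - 1e-9 | a$length_mm > 6 + 1e-9))
      return("ant lengths must lie in [4, 6] mm")
    if (any(sqrt(a$x_cm^2 + a$y_cm^2) > object@arenaRadiusCm))
      return("all ants must lie inside the arena")
  }
  if (object@arenaRadiusCm <= 0) return("arenaRadiusCm must be positive")
  if (object@resolution <= 0) return("resolution must be positive")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' PlatformROI: foraging-platform region and bridge gate
#'
#' @slot polygon n x 2 matrix of pixel coordinates delimiting the platform
#'   (simple, non-self-intersecting).
#' @slot gate 2 x 2 matrix (rows: start, end) of the directed gate segment;
#'   crossing with the gate direction on the left (positive side) counts as
#'   entering.
#'
#' @exportClass PlatformROI
setClass("PlatformROI",
  representation(polygon = "matrix", gate = "matrix")
)

setValidity("PlatformROI", function(object) {
  if (ncol(object@polygon) != 2L || nrow(object@polygon) < 3L)
    return("polygon must be an n x 2 matrix with n >= 3")
  if (!all(dim(object@gate) == c(2L, 2L)))
    return("gate must be a 2 x 2 matrix (start and end point)")
  if (sum((object@gate[2, ] - object@gate[1, ])^2) == 0)
    return("gate must have nonzero length")
  if (.polygonSelfIntersects(object@polygon))
    return("polygon must be simple (non-self-intersecting)")
  TRUE
})
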
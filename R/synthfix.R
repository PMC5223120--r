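# Ground-truthed synthetic arena scenes: light noisy floor, dark rounded
# seeds (1-2.5 mm), dark elongated ants (4-6 mm), optional two-camera split
# with per-camera luminosity offsets and a known homography.

#' Create a SceneTruth
#'
#' @param seeds data.frame with columns `x_cm`, `y_cm`, `width_mm` and
#'   optional `appear`, `disappear` (frame indices, inclusive; defaults 1
#'   and Inf).
#' @param ants data.frame with columns `x_cm`, `y_cm`, `length_mm`,
#'   `heading` (radians); may be empty.
#' @param arenaRadiusCm arena radius in cm.
#' @param resolution mm per pixel (default 0.677).
#' @param noiseSigma Gaussian pixel noise sd in grey levels (default 5).
#' @param cameraOffsets per-camera luminance offsets for two-view renders
#'   (default +10 / -10 grey levels).
#' @param floorLevel,seedLevel floor and object luminance (default 200 and
#'   30).
#' @param seed RNG seed for rendering noise and ant motion.
#' @return a [SceneTruth-class].
#' @export
sceneTruth <- function(seeds = NULL, ants = NULL, arenaRadiusCm = 15,
                       resolution = 0.677, noiseSigma = 5,
                       cameraOffsets = c(10, -10), floorLevel = 200,
                       seedLevel = 30, seed = 0) {
  if (is.null(seeds))
    seeds <- data.frame(x_cm = numeric(), y_cm = numeric(),
                        width_mm = numeric())
  if (is.null(seeds$appear)) seeds$appear <- if (nrow(seeds)) 1 else numeric()
  if (is.null(seeds$disappear))
    seeds$disappear <- if (nrow(seeds)) Inf else numeric()
  if (is.null(ants))
    ants <- data.frame(x_cm = numeric(), y_cm = numeric(),
                       length_mm = numeric(), heading = numeric())
  new("SceneTruth", seeds = seeds, ants = ants,
      arenaRadiusCm = arenaRadiusCm, resolution = resolution,
      noiseSigma = noiseSigma, cameraOffsets = cameraOffsets,
      floorLevel = floorLevel, seedLevel = seedLevel,
      seed = as.integer(seed))
}

#' Random scene layout
#'
#' Seeds are placed by dart throwing with a minimum separation; widths are
#' uniform in [1, 2.5] mm. Ants are placed uniformly with random headings
#' and lengths uniform in [4, 6] mm.
#'
#' @param nSeeds,nAnts object counts.
#' @param arenaRadiusCm arena radius (cm).
#' @param minSepCm minimum seed separation (default 1.2 cm).
#' @param margin fraction of the radius kept free of objects at the border
#'   (default 0.06).
#' @param seedAppear,seedDisappear frame schedule applied to every seed.
#' @param seed RNG seed.
#' @param ... forwarded to [sceneTruth()].
#' @return a [SceneTruth-class].
#' @export
randomScene <- function(nSeeds, nAnts = 0L, arenaRadiusCm = 15,
                        minSepCm = 1.2, margin = 0.06, seedAppear = 1,
                        seedDisappear = Inf, seed = 0, ...) {
  Rmax <- arenaRadiusCm * (1 - margin)
  withSeed(seed, {
    pts <- matrix(numeric(), 0L, 2L)
    guard <- 0L
    while (nrow(pts) < nSeeds) {
      r <- Rmax * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
      p <- c(r * cos(a), r * sin(a))
      if (nrow(pts) == 0L ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= minSepCm)
        pts <- rbind(pts, p)
      guard <- guard + 1L
      if (guard > 200000L) stop("could not place seeds at this separation")
    }
    seeds <- if (nSeeds > 0)
      data.frame(x_cm = pts[, 1], y_cm = pts[, 2],
                 width_mm = stats::runif(nSeeds, 1, 2.5),
                 appear = seedAppear, disappear = seedDisappear)
    else NULL
    ants <- if (nAnts > 0) {
      r <- Rmax * sqrt(stats::runif(nAnts))
      a <- stats::runif(nAnts, 0, 2 * pi)
      data.frame(x_cm = r * cos(a), y_cm = r * sin(a),
                 length_mm = stats::runif(nAnts, 4, 6),
                 heading = stats::runif(nAnts, 0, 2 * pi))
    } else NULL
    sceneTruth(seeds = seeds, ants = ants, arenaRadiusCm = arenaRadiusCm,
               seed = seed, ...)
  })
}

# image geometry helpers -----------------------------------------------------

.sceneDims <- function(truth) {
  side <- as.integer(ceiling(2 * truth@arenaRadiusCm * 10 / truth@resolution))
  c(H = side, W = side)
}

#' Nest centre of a rendered scene, in 0-based pixel coordinates
#' @param truth a [SceneTruth-class].
#' @export
sceneNestCentre <- function(truth) {
  d <- .sceneDims(truth)
  c((d["W"] - 1) / 2, (d["H"] - 1) / 2)
}

# Rendered seed core radius (px) for a physical width (mm). The mapping is
# an empirical calibration, not ideal disc area: anti-aliased rasterization
# and the dark-core threshold are tuned so that default segmentation yields
# blob sizes inside the 5-19 px gate for widths 1-2.5 mm at 0.677 mm/px.
.seedRenderRadius <- function(width_mm, resolution) {
  (1.28 + 0.46 * width_mm) * (0.677 / resolution)
}

# supersampled coverage stamp of a disc; returns list(rows, cols, cov)
.discCoverage <- function(cxPx, cyPx, rPx, H, W, ss = 4L) {
  x0 <- max(0L, floor(cxPx - rPx - 1)); x1 <- min(W - 1L, ceiling(cxPx + rPx + 1))
  y0 <- max(0L, floor(cyPx - rPx - 1)); y1 <- min(H - 1L, ceiling(cyPx + rPx + 1))
  if (x1 < x0 || y1 < y0) return(NULL)
  off <- ((seq_len(ss) - 0.5) / ss) - 0.5
  xs <- x0:x1; ys <- y0:y1
  subx <- outer(xs, off, "+")  # nx x ss
  suby <- outer(ys, off, "+")
  dx2 <- (subx - cxPx)^2       # nx x ss
  dy2 <- (suby - cyPx)^2
  # coverage[y, x] = mean over ss^2 subpixels of (dx2 + dy2 <= r^2)
  nx <- length(xs); ny <- length(ys)
  r2 <- rPx^2
  cov <- matrix(0, ny, nx)
  for (i in seq_len(ss)) {
    dyi <- dy2[, i]
    for (j in seq_len(ss)) {
      cov <- cov + (outer(dyi, dx2[, j], "+") <= r2)
    }
  }
  list(rows = ys + 1L, cols = xs + 1L, cov = cov / ss^2)
}

# supersampled coverage of a capsule (segment with round caps)
.capsuleCoverage <- function(cxPx, cyPx, heading, lenPx, hwPx, H, W, ss = 4L) {
  ux <- cos(heading); uy <- sin(heading)
  hx <- ux * lenPx / 2; hy <- uy * lenPx / 2
  ext <- lenPx / 2 + hwPx + 1
  x0 <- max(0L, floor(cxPx - ext)); x1 <- min(W - 1L, ceiling(cxPx + ext))
  y0 <- max(0L, floor(cyPx - ext)); y1 <- min(H - 1L, ceiling(cyPx + ext))
  if (x1 < x0 || y1 < y0) return(NULL)
  off <- ((seq_len(ss) - 0.5) / ss) - 0.5
  xs <- x0:x1; ys <- y0:y1
  nx <- length(xs); ny <- length(ys)
  cov <- matrix(0, ny, nx)
  hl <- lenPx / 2
  for (i in seq_len(ss)) {
    sy <- ys + off[i] - cyPx
    for (j in seq_len(ss)) {
      sx <- xs + off[j] - cxPx
      # distance from subpixel to the segment through the origin along u
      t <- outer(sy * uy, sx * ux, "+")          # ny x nx of y*uy + x*ux
      tc <- pmin(pmax(t, -hl), hl)
      dx <- outer(rep(1, ny), sx) - tc * ux
      dy <- outer(sy, rep(1, nx)) - tc * uy
      cov <- cov + (dx * dx + dy * dy <= hwPx^2)
    }
  }
  list(rows = ys + 1L, cols = xs + 1L, cov = cov / ss^2)
}

#' Render one synthetic frame
#'
#' Renders the arena scene at `frameIndex`: a light floor with Gaussian
#' pixel noise, seeds visible per their appear/disappear schedule as dark
#' anti-aliased discs, ants as dark elongated capsules. In `"two"` view
#' mode, two overlapping vertical slices are returned with their own
#' independent noise, per-camera luminosity offsets and the ground-truth
#' homography mapping view B into view A's frame.
#'
#' @param truth a [SceneTruth-class].
#' @param frameIndex frame number (controls the seed schedule and the
#'   per-frame noise stream).
#' @param ants optional data.frame overriding the truth's ant states for
#'   this frame (columns `x_cm`, `y_cm`, `length_mm`, `heading`).
#' @param view "full" (one [ArenaFrame-class]) or "two" (list with `a`,
#'   `b`, `h`).
#' @param overlap fractional horizontal overlap of the two views
#'   (default 0.25).
#' @return an ArenaFrame, or a list for two-view mode.
#' @export
renderFrame <- function(truth, frameIndex = 1L, ants = NULL,
                        view = c("full", "two"), overlap = 0.25) {
  view <- match.arg(view)
  d <- .sceneDims(truth)
  H <- d[["H"]]; W <- d[["W"]]
  res <- truth@resolution
  nest <- sceneNestCentre(truth)
  lum <- matrix(truth@floorLevel, H, W)
  depth <- truth@floorLevel - truth@seedLevel

  stamp <- function(cv) {
    if (is.null(cv)) return()
    cur <- lum[cv$rows, cv$cols]
    lum[cv$rows, cv$cols] <<- pmin(cur, truth@floorLevel - depth * cv$cov)
  }

  sd <- truth@seeds
  if (nrow(sd)) {
    vis <- sd$appear <= frameIndex & sd$disappear >= frameIndex
    for (i in which(vis)) {
      p <- cmToPx(c(sd$x_cm[i], sd$y_cm[i]), res, nest)
      stamp(.discCoverage(p[1], p[2], .seedRenderRadius(sd$width_mm[i], res),
                          H, W))
    }
  }
  if (is.null(ants)) ants <- truth@ants
  if (nrow(ants)) {
    for (i in seq_len(nrow(ants))) {
      p <- cmToPx(c(ants$x_cm[i], ants$y_cm[i]), res, nest)
      stamp(.capsuleCoverage(p[1], p[2], ants$heading[i],
                             ants$length_mm[i] / res, 1.7, H, W))
    }
  }

  makeView <- function(cols0, camIdx, camId) {
    sub <- lum[, cols0 + 1L, drop = FALSE]
    hs <- ncol(sub)
    px <- array(0, dim = c(H, hs, 3L))
    offset <- if (camIdx > 0) truth@cameraOffsets[camIdx] else 0
    noisySeed <- .deriveSeed(truth@seed, frameIndex * 17L + camIdx)
    withSeed(noisySeed, {
      for (ch in 1:3) {
        noise <- if (truth@noiseSigma > 0)
          matrix(stats::rnorm(H * hs, 0, truth@noiseSigma), H, hs)
        else 0
        px[, , ch] <- sub + offset + noise
      }
    })
    arenaFrame(round(.clip255(px)), resolution = res,
               timestamp = (frameIndex - 1) * 10, cameraId = camId)
  }

  if (view == "full") return(makeView(0:(W - 1L), 0L, "full"))
  wA <- ceiling(W * (0.5 + overlap / 2))
  ox <- W - wA  # view B starts at full-frame column ox
  a <- makeView(0:(wA - 1L), 1L, "camA")
  b <- makeView(ox:(W - 1L), 2L, "camB")
  h <- rbind(c(1, 0, ox), c(0, 1, 0), c(0, 0, 1))
  list(a = a, b = b, h = h)
}

#' Render a frame sequence with moving ants
#'
#' Seeds follow their appear/disappear schedule. Ants perform a bounded
#' random walk whose per-frame displacement is `antStepFactor` times their
#' body length (so moving ants never persist across the 2-of-3 temporal
#' filter), bouncing back towards the centre at the arena border.
#'
#' @param truth a [SceneTruth-class].
#' @param nFrames number of frames (>= 3).
#' @param view "full" or "two" (see [renderFrame()]).
#' @param antStepFactor displacement per frame in body lengths
#'   (default 1.5; must be >= 1).
#' @param dt frame interval in minutes (metadata only).
#' @param overlap two-view overlap fraction.
#' @return list with `frames` (list of renders), `antTracks` (data.frame:
#'   `frame`, `ant_id`, `x_cm`, `y_cm`, `length_mm`, `heading`),
#'   `seedTables` (per-frame data.frame of visible seeds) and `truth`.
#' @export
makeSequence <- function(truth, nFrames, view = c("full", "two"),
                         antStepFactor = 1.5, dt = 10, overlap = 0.25) {
  view <- match.arg(view)
  if (nFrames < 3L) stop("need at least 3 frames")
  if (antStepFactor < 1) stop("ants must displace by >= one body length")
  ants <- truth@ants
  nA <- nrow(ants)
  Rmax <- truth@arenaRadiusCm * 0.92
  tracks <- vector("list", nFrames)
  withSeed(.deriveSeed(truth@seed, 555L), {
    st <- ants
    for (f in seq_len(nFrames)) {
      if (nA > 0 && f > 1L) {
        st$heading <- st$heading + stats::runif(nA, -0.7, 0.7)
        stepCm <- antStepFactor * st$length_mm / 10
        nx <- st$x_cm + stepCm * cos(st$heading)
        ny <- st$y_cm + stepCm * sin(st$heading)
        out <- sqrt(nx^2 + ny^2) > Rmax
        if (any(out)) {
          st$heading[out] <- atan2(-st$y_cm[out], -st$x_cm[out]) +
            stats::runif(sum(out), -0.3, 0.3)
          nx[out] <- st$x_cm[out] +
            stepCm[out] * cos(st$heading[out])
          ny[out] <- st$y_cm[out] + stepCm[out] * sin(st$heading[out])
        }
        st$x_cm <- nx; st$y_cm <- ny
      }
      tracks[[f]] <- if (nA > 0)
        data.frame(frame = f, ant_id = seq_len(nA), x_cm = st$x_cm,
                   y_cm = st$y_cm, length_mm = st$length_mm,
                   heading = st$heading)
      else
        data.frame(frame = integer(), ant_id = integer(), x_cm = numeric(),
                   y_cm = numeric(), length_mm = numeric(),
                   heading = numeric())
    }
  })
  frames <- vector("list", nFrames)
  seedTables <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    antsF <- tracks[[f]][, c("x_cm", "y_cm", "length_mm", "heading"),
                         drop = FALSE]
    frames[[f]] <- renderFrame(truth, f, ants = antsF, view = view,
                               overlap = overlap)
    sd <- truth@seeds
    seedTables[[f]] <- sd[sd$appear <= f & sd$disappear >= f, , drop = FALSE]
  }
  list(frames = frames, antTracks = do.call(rbind, tracks),
       seedTables = seedTables, truth = truth, dt = dt)
}
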
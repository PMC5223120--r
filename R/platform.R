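# Foraging-platform census: remaining diaspores and ant flow across the
# bridge gate.

#' Count diaspores remaining on the foraging platform
#'
#' Dark pixels (luminance <= `darkThreshold`) inside the platform polygon are
#' pooled into blobs; blobs larger than the seed size gate are treated as
#' ants standing on the platform and subtracted:
#' `D_track = n_blobs - n_blobs_larger_than_seedMaxPx`.
#'
#' @param frame an [ArenaFrame-class].
#' @param roi a [platformROI()].
#' @param params a [segmentationParams()].
#' @return integer diaspore count.
#' @export
countPlatformDiaspores <- function(frame, roi, params = segmentationParams()) {
  px <- pixels(frame)
  H <- dim(px)[1]; W <- dim(px)[2]
  poly <- roi@polygon
  if (any(poly[, 1] < 0 | poly[, 1] > W - 1 | poly[, 2] < 0 |
          poly[, 2] > H - 1))
    stop("platform polygon lies outside the frame")
  dark <- luminance(px) <= params@darkThreshold
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  inPoly <- matrix(.pointInPolygon(cbind(gx, gy), poly), H, W)
  blobs <- detectBlobs(dark & inPoly, params)
  nrow(blobs) - sum(blobs$size_px > params@seedMaxPx)
}

# Signed side of point(s) p relative to the directed gate line g0 -> g1:
# positive on the left of the direction of travel.
.gateSide <- function(p, g0, g1) {
  (g1[1] - g0[1]) * (p[, 2] - g0[2]) - (g1[2] - g0[2]) * (p[, 1] - g0[1])
}

#' Count directed gate crossings of trajectories
#'
#' For each trajectory, every transversal crossing of the gate segment is
#' counted: moving from the negative to the positive side of the directed
#' gate line increments the inflow, the opposite movement the outflow.
#' A crossing is only counted when the intersection point lies within the
#' gate segment. Points exactly on the gate line are resolved towards "no
#' crossing": the trajectory keeps its previous side until it moves off the
#' line.
#'
#' @param trajectories data.frame with columns `track_id`, `timestamp`,
#'   `x_px`, `y_px`.
#' @param roi a [platformROI()].
#' @return named numeric vector `c(inflow = ..., outflow = ...)`.
#' @export
countGateCrossings <- function(trajectories, roi) {
  g0 <- roi@gate[1, ]; g1 <- roi@gate[2, ]
  glen2 <- sum((g1 - g0)^2)
  inflow <- 0L; outflow <- 0L
  for (id in unique(trajectories$track_id)) {
    tr <- trajectories[trajectories$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (any(diff(tr$timestamp) <= 0))
      stop("timestamps must be strictly increasing within a track")
    p <- cbind(tr$x_px, tr$y_px)
    s <- sign(.gateSide(p, g0, g1))
    prevSide <- 0
    prevPt <- p[1, ]
    for (i in seq_len(nrow(p))) {
      if (s[i] == 0) next  # on the line: no side change yet
      if (prevSide != 0 && s[i] != prevSide) {
        # segment from the last off-line point to the current point
        a <- prevPt; b <- p[i, ]
        # intersection of segment a-b with the infinite gate line,
        # parameterized along the gate
        da <- .gateSide(matrix(a, 1), g0, g1)
        db <- .gateSide(matrix(b, 1), g0, g1)
        t <- da / (da - db)
        q <- a + t * (b - a)
        u <- sum((q - g0) * (g1 - g0)) / glen2
        if (u >= 0 && u <= 1) {
          if (s[i] > 0) inflow <- inflow + 1L else outflow <- outflow + 1L
        }
      }
      prevSide <- s[i]
      prevPt <- p[i, ]
    }
  }
  c(inflow = inflow, outflow = outflow)
}

#' Platform census time series
#'
#' Convenience wrapper producing the flow/census table for a sequence of
#' frames and a set of trajectories: per timestamp, cumulative inflow and
#' outflow up to that time and the diaspore count `D_track`.
#'
#' @param frames list of [ArenaFrame-class].
#' @param roi a [platformROI()].
#' @param trajectories data.frame as in [countGateCrossings()].
#' @param params a [segmentationParams()].
#' @return data.frame with columns `timestamp`, `cum_inflow`, `cum_outflow`,
#'   `D_track`.
#' @export
platformSeries <- function(frames, roi, trajectories = NULL,
                           params = segmentationParams()) {
  ts <- vapply(frames, timestamp, numeric(1))
  d <- vapply(frames, countPlatformDiaspores, integer(1), roi = roi,
              params = params)
  cumin <- integer(length(frames)); cumout <- integer(length(frames))
  if (!is.null(trajectories) && nrow(trajectories) > 0) {
    for (i in seq_along(ts)) {
      sub <- trajectories[trajectories$timestamp <= ts[i], , drop = FALSE]
      keep <- table(sub$track_id) >= 2
      sub <- sub[sub$track_id %in% names(keep)[keep], , drop = FALSE]
      if (nrow(sub) > 0) {
        cr <- countGateCrossings(sub, roi)
        cumin[i] <- cr["inflow"]; cumout[i] <- cr["outflow"]
      }
    }
  }
  data.frame(timestamp = ts, cum_inflow = cumin, cum_outflow = cumout,
             D_track = d)
}
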
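# Seed occupancy episodes: linking per-frame detections over time,
# redispersal distances and rejection dynamics.

#' Link per-frame seed detections into occupancy episodes
#'
#' A seed detected within `matchRadiusPx` of an open episode's position
#' continues that episode (the episode position is the running mean of its
#' detections); otherwise a new episode opens. An episode closes at the
#' first frame with no matching detection. Matching within a frame is
#' greedy by increasing distance, each episode and each detection being
#' used at most once.
#'
#' An episode's duration counts its occupied frames:
#' `duration_min = (last_frame - first_frame + 1) * dt`.
#'
#' Frames separated by more than `gapFactor * dt` minutes (e.g. a night
#' period with no imaging) define gaps; episodes spanning a gap are flagged
#' `gap = TRUE` so they can be excluded from duration statistics.
#'
#' @param detections list of [FrameDetections-class] in temporal order
#'   (strictly increasing frame indices).
#' @param matchRadiusPx association radius in pixels (default 3, about 2 mm
#'   at 0.677 mm/pixel: seeds are static, anything farther is a
#'   redispersal).
#' @param dt frame interval in minutes.
#' @param gapFactor multiples of `dt` above which an inter-frame interval is
#'   a gap.
#' @return data.frame with one row per episode: `episode_id`, `x_cm`,
#'   `y_cm`, `x_px`, `y_px`, `first_frame`, `last_frame`, `first_ts`,
#'   `last_ts`, `duration_min`, `dist_nest_cm`, `n_frames`, `gap`.
#' @export
linkEpisodes <- function(detections, matchRadiusPx = 3, dt = 10,
                         gapFactor = 1.5) {
  fi <- vapply(detections, function(d) d@frameIndex, integer(1))
  if (any(diff(fi) <= 0)) stop("frames must be ordered by increasing index")
  ts <- vapply(detections, function(d) d@timestamp, numeric(1))
  gapAfter <- c(diff(ts) > gapFactor * dt, FALSE)

  eps <- list()   # closed episodes
  open <- list()  # each: list(sx, sy, scx, scy, n, first, firstTs, gap)
  closeEpisode <- function(e, lastFrame, lastTs) {
    data.frame(
      x_cm = e$scx / e$n, y_cm = e$scy / e$n,
      x_px = e$sx / e$n, y_px = e$sy / e$n,
      first_frame = e$first, last_frame = lastFrame,
      first_ts = e$firstTs, last_ts = lastTs,
      n_frames = e$n, gap = e$gap)
  }

  prevFrame <- NA_integer_; prevTs <- NA_real_
  for (k in seq_along(detections)) {
    det <- detections[[k]]
    sd <- det@seeds
    nOpen <- length(open)
    nDet <- nrow(sd)
    matchedE <- rep(FALSE, nOpen)
    matchedD <- rep(FALSE, nDet)
    if (nOpen > 0 && nDet > 0) {
      ex <- vapply(open, function(e) e$sx / e$n, numeric(1))
      ey <- vapply(open, function(e) e$sy / e$n, numeric(1))
      dmat <- sqrt(outer(ex, sd$x_px, "-")^2 + outer(ey, sd$y_px, "-")^2)
      ord <- order(dmat)
      for (idx in ord) {
        if (dmat[idx] > matchRadiusPx) break
        i <- (idx - 1L) %% nOpen + 1L
        j <- (idx - 1L) %/% nOpen + 1L
        if (matchedE[i] || matchedD[j]) next
        matchedE[i] <- TRUE; matchedD[j] <- TRUE
        e <- open[[i]]
        e$sx <- e$sx + sd$x_px[j]; e$sy <- e$sy + sd$y_px[j]
        e$scx <- e$scx + sd$x_cm[j]; e$scy <- e$scy + sd$y_cm[j]
        e$n <- e$n + 1L
        open[[i]] <- e
      }
    }
    # close unmatched episodes at the previous frame
    if (nOpen > 0) {
      for (i in which(!matchedE))
        eps[[length(eps) + 1L]] <- closeEpisode(open[[i]], prevFrame, prevTs)
      open <- open[matchedE]
    }
    # new episodes for unmatched detections
    if (nDet > 0) {
      for (j in which(!matchedD)) {
        open[[length(open) + 1L]] <- list(
          sx = sd$x_px[j], sy = sd$y_px[j],
          scx = sd$x_cm[j], scy = sd$y_cm[j], n = 1L,
          first = det@frameIndex, firstTs = det@timestamp, gap = FALSE)
      }
    }
    # flag episodes that will span a gap following this frame
    if (gapAfter[k] && length(open) > 0) {
      for (i in seq_along(open)) open[[i]]$gap <- TRUE
    }
    prevFrame <- det@frameIndex; prevTs <- det@timestamp
  }
  for (e in open)
    eps[[length(eps) + 1L]] <- closeEpisode(e, prevFrame, prevTs)

  if (length(eps) == 0L) {
    out <- data.frame(episode_id = integer(), x_cm = numeric(),
                      y_cm = numeric(), x_px = numeric(), y_px = numeric(),
                      first_frame = integer(), last_frame = integer(),
                      first_ts = numeric(), last_ts = numeric(),
                      duration_min = numeric(), dist_nest_cm = numeric(),
                      n_frames = integer(), gap = logical())
    return(out)
  }
  out <- do.call(rbind, eps)
  out <- out[order(out$first_frame, out$x_px), , drop = FALSE]
  out$episode_id <- seq_len(nrow(out))
  out$duration_min <- (out$last_frame - out$first_frame + 1) * dt
  out$dist_nest_cm <- sqrt(out$x_cm^2 + out$y_cm^2)
  rownames(out) <- NULL
  out[, c("episode_id", "x_cm", "y_cm", "x_px", "y_px", "first_frame",
          "last_frame", "first_ts", "last_ts", "duration_min",
          "dist_nest_cm", "n_frames", "gap")]
}

#' Minimum redispersal distances
#'
#' For each episode closing at frame t (except those still open at the end
#' of the observation), the candidates are episodes opening within the next
#' `windowFrames` frames (t + 1 .. t + windowFrames); the minimum Euclidean
#' distance (cm) from the closing episode's position to a candidate is the
#' redispersal distance. Episodes with no candidate keep `NA` (undefined,
#' never zero-filled).
#'
#' @param episodes data.frame from [linkEpisodes()].
#' @param windowFrames candidate window after closure, in frames (default 2,
#'   i.e. 20 minutes at a 10-minute frame interval).
#' @param lastFrame final observed frame index; episodes closing there are
#'   not redispersals (default: max `last_frame` in the table).
#' @return `episodes` with an added `redisp_dist_cm` column.
#' @export
redispersalDistances <- function(episodes, windowFrames = 2,
                                 lastFrame = NULL) {
  if (nrow(episodes) == 0L) {
    episodes$redisp_dist_cm <- numeric(0)
    return(episodes)
  }
  if (is.null(lastFrame)) lastFrame <- max(episodes$last_frame)
  episodes$redisp_dist_cm <- NA_real_
  for (i in seq_len(nrow(episodes))) {
    t <- episodes$last_frame[i]
    if (t >= lastFrame) next
    cand <- episodes$first_frame >= t + 1 &
      episodes$first_frame <= t + windowFrames
    cand[i] <- FALSE
    if (!any(cand)) next
    d <- sqrt((episodes$x_cm[cand] - episodes$x_cm[i])^2 +
              (episodes$y_cm[cand] - episodes$y_cm[i])^2)
    episodes$redisp_dist_cm[i] <- min(d)
  }
  episodes
}

#' Rejection dynamics
#'
#' Per-frame count of open episodes (seeds present in the arena) and,
#' when a manual end-of-experiment count is supplied, the rejected fraction
#' `eta_rejected(t) = count(t) / sCountEnd`.
#'
#' @param episodes data.frame from [linkEpisodes()].
#' @param frames integer vector of frame indices to evaluate.
#' @param sCountEnd optional manual final seed count (> 0).
#' @return data.frame with columns `frame`, `n_seeds` and (when `sCountEnd`
#'   is given) `eta_rejected`; the final automated count is attached as
#'   attribute `S_track_end`.
#' @export
rejectionDynamics <- function(episodes, frames, sCountEnd = NULL) {
  counts <- vapply(frames, function(f)
    sum(episodes$first_frame <= f & episodes$last_frame >= f), integer(1))
  out <- data.frame(frame = frames, n_seeds = counts)
  if (!is.null(sCountEnd)) {
    if (sCountEnd == 0) stop("sCountEnd must be positive")
    out$eta_rejected <- counts / sCountEnd
  }
  attr(out, "S_track_end") <- if (length(counts)) counts[length(counts)] else 0L
  out
}

#' Write episodes to CSV
#'
#' @param episodes data.frame from [linkEpisodes()] (optionally with
#'   redispersal distances).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEpisodesCSV <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE, na = "")
  invisible(path)
}
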
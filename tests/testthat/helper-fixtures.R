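# Shared fixtures and independent oracles used across the suite.

# Brute-force BFS connected-component labeling (independent oracle for
# labelComponents, both connectivities).
bfsLabel <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else rbind(c(-1,0),c(1,0),c(0,-1),c(0,1))
  cur <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# number of distinct labels per connected structure, invariant to label order
labelPartition <- function(lab) {
  idx <- which(lab > 0L)
  split(idx, lab[idx]) |> lapply(sort) |> unname() |>
    (\(x) x[order(vapply(x, min, numeric(1)))])()
}

# minimal FrameDetections builder for tracking tests
makeDetections <- function(frameIndex, xs, ys = rep(0, length(xs)),
                           timestamp = frameIndex * 10, resolution = 0.677) {
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      size_px = integer(), x_cm = numeric(),
                      y_cm = numeric())
  seeds <- if (length(xs))
    data.frame(x_px = xs, y_px = ys, size_px = rep(10L, length(xs)),
               x_cm = xs * resolution / 10, y_cm = -ys * resolution / 10)
  else empty
  new("FrameDetections", frameIndex = as.integer(frameIndex),
      timestamp = timestamp, seeds = seeds, ants = empty, discarded = empty)
}

# flat grey frame with optional dark rectangles: list(x0, y0, x1, y1, value)
greyFrame <- function(H, W, level = 200, patches = list(), resolution = 0.677) {
  m <- matrix(level, H, W)
  for (p in patches)
    m[(p[2]:p[4]) + 1, (p[1]:p[3]) + 1] <- p[5]
  arenaFrame(m, resolution = resolution)
}
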
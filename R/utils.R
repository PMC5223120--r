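# Internal numerical helpers shared across modules.

#' Luminance of an RGB array
#'
#' Luminance is defined throughout the package as the unweighted channel mean
#' (R + G + B) / 3, in grey levels.
#'
#' @param px H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
luminance <- function(px) {
  (px[, , 1] + px[, , 2] + px[, , 3]) / 3
}

.clip255 <- function(x) pmin(pmax(x, 0), 255)

# Trapezoidal integral of y over x (x increasing).
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream. All Monte-Carlo entry points route their `seed` argument here.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shift a matrix by (dr, dc), padding with `fill`.
.shiftMat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Label connected components of a binary mask
#'
#' Vectorized min-label propagation: every foreground pixel starts with a
#' unique label and repeatedly takes the minimum label over itself and its
#' neighbours until a fixed point, which assigns one label per connected
#' component. Labels are then renumbered 1..k in raster order.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 for background.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(Inf, H, W)
  fg <- which(mask)
  if (!length(fg)) return(matrix(0L, H, W))
  lab[fg] <- as.numeric(fg)
  shifts <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  repeat {
    cur <- lab
    for (s in shifts)
      cur <- pmin(cur, .shiftMat(lab, s[1], s[2], Inf))
    cur[!mask] <- Inf
    if (identical(cur, lab)) break
    lab <- cur
  }
  out <- matrix(0L, H, W)
  out[fg] <- match(lab[fg], sort(unique(lab[fg])))
  out
}

# Extract blobs (size + centroid, 0-based pixel coords) from a label matrix.
.blobsFromLabels <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), size_px = integer(),
                      x_px = numeric(), y_px = numeric()))
  H <- nrow(lab)
  row <- (idx - 1L) %% H          # 0-based y
  col <- (idx - 1L) %/% H         # 0-based x
  dt <- data.table::data.table(label = lab[idx], x = col, y = row)
  agg <- dt[, list(size_px = .N, x_px = mean(x), y_px = mean(y)),
            by = "label"]
  data.table::setorder(agg, label)
  as.data.frame(agg[, c("label", "size_px", "x_px", "y_px"), with = FALSE])
}

# Even-odd point-in-polygon test (vertices n x 2, points m x 2).
# Points exactly on an edge may fall on either side; callers that care use a
# tolerance of their own.
.pointInPolygon <- function(pts, poly) {
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Proper-intersection test between segments (p1,p2) and (p3,p4).
.segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

.polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  segs <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      # skip adjacent segments (they share an endpoint)
      if (j == i || abs(j - i) == 1L || (i == 1L && j == n)) next
      if (.segmentsIntersect(poly[segs[i, 1], ], poly[segs[i, 2], ],
                             poly[segs[j, 1], ], poly[segs[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

# Bilinear sampling of an H x W x 3 array at 0-based fractional pixel
# coordinates. Returns an n x 3 matrix; NA outside the image.
.bilinearSample <- function(px, x, y) {
  H <- dim(px)[1]; W <- dim(px)[2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp the 2x2 support to the image so border pixels sample correctly
  x0c <- pmin(pmax(x0, 0), W - 1); x1c <- pmin(x0c + 1, W - 1)
  y0c <- pmin(pmax(y0, 0), H - 1); y1c <- pmin(y0c + 1, H - 1)
  valid <- x >= -0.5 & x <= W - 0.5 & y >= -0.5 & y <= H - 0.5
  out <- matrix(NA_real_, length(x), 3L)
  if (!any(valid)) return(out)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  for (ch in 1:3) {
    base <- (ch - 1L) * H * W
    v <- w00 * px[base + y0c + 1L + H * x0c] +
         w10 * px[base + y0c + 1L + H * x1c] +
         w01 * px[base + y1c + 1L + H * x0c] +
         w11 * px[base + y1c + 1L + H * x1c]
    out[, ch] <- ifelse(valid, v, NA_real_)
  }
  out
}

# Nearest-neighbour sampling variant (bit-exact for integer warps).
.nearestSample <- function(px, x, y) {
  H <- dim(px)[1]; W <- dim(px)[2]
  xi <- round(x); yi <- round(y)
  valid <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
  out <- matrix(NA_real_, length(x), 3L)
  xi <- pmin(pmax(xi, 0), W - 1); yi <- pmin(pmax(yi, 0), H - 1)
  for (ch in 1:3) {
    base <- (ch - 1L) * H * W
    v <- px[base + yi + 1L + H * xi]
    out[, ch] <- ifelse(valid, v, NA_real_)
  }
  out
}
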
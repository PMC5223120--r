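# Stitching of two overlapping, exposure-mismatched camera views:
# luminosity compensation, homography estimation/application, lens
# undistortion, and hard stitch-line compositing (no blending).

#' Compensate luminosity across a set of images
#'
#' Computes the global mean luminance of all input images and shifts each
#' image by an additive offset (applied equally to all channels, clipped to
#' [0, 255]) so that every image matches the global mean. An additive offset
#' is exposure-like and preserves within-image contrast ordering.
#'
#' @param frames list of [ArenaFrame-class] objects.
#' @return list of compensated ArenaFrames (same order, dimensions unchanged).
#' @examples
#' a <- arenaFrame(array(100, dim = c(4, 4, 3)))
#' b <- arenaFrame(array(120, dim = c(4, 4, 3)))
#' out <- compensateLuminosity(list(a, b))
#' mean(pixels(out[[1]]))  # 110
#' @export
compensateLuminosity <- function(frames) {
  if (length(frames) == 0L) stop("no images")
  means <- vapply(frames, function(f) mean(luminance(pixels(f))), numeric(1))
  global <- mean(means)
  lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    off <- global - means[i]
    if (off == 0) return(f)
    f@pixels <- .clip255(f@pixels + off)
    f
  })
}

#' Estimate a homography from point correspondences
#'
#' Normalized direct linear transform (DLT): both point sets are translated
#' to their centroid and scaled to mean distance sqrt(2), the 2n x 9 design
#' matrix is solved by SVD (total least squares over all pairs), and the
#' result is denormalized and scaled so that H[3, 3] = 1.
#'
#' @param src,dst n x 2 matrices of corresponding pixel coordinates
#'   (n >= 4, no 3 source points collinear). `src` may also be a data.frame
#'   with columns `src_x`, `src_y`, `dst_x`, `dst_y`, in which case `dst` is
#'   ignored.
#' @return 3 x 3 homography matrix mapping src -> dst, H[3, 3] = 1.
#' @examples
#' src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
#' estimateHomography(src, src + rep(c(5, -3), each = 4))
#' @export
estimateHomography <- function(src, dst = NULL) {
  if (is.data.frame(src) && all(c("src_x", "src_y", "dst_x", "dst_y") %in%
                                names(src))) {
    dst <- cbind(src$dst_x, src$dst_y)
    src <- cbind(src$src_x, src$src_y)
  }
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n) stop("insufficient correspondences")
  norm2d <- function(p) {
    c0 <- colMeans(p)
    q <- sweep(p, 2, c0)
    s <- sqrt(2) / mean(sqrt(rowSums(q^2)))
    if (!is.finite(s)) stop("insufficient correspondences")
    T <- rbind(c(s, 0, -s * c0[1]), c(0, s, -s * c0[2]), c(0, 0, 1))
    list(p = q * s, T = T)
  }
  ns <- norm2d(src); nd <- norm2d(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  z <- rep(0, n); o <- rep(1, n)
  A <- rbind(
    cbind(-x, -y, -o, z, z, z, u * x, u * y, u),
    cbind(z, z, z, -x, -y, -o, v * x, v * y, v))
  sv <- svd(A, nu = 0, nv = 9)
  # a near-zero second-smallest singular value signals a degenerate
  # configuration (e.g. collinear source points): the solution is not unique
  if (sv$d[8] < max(sv$d) * 1e-8) stop("insufficient correspondences")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12 || abs(det(H)) < 1e-12)
    stop("insufficient correspondences")
  H / H[3, 3]
}

#' Apply a homography to points
#'
#' @param pts length-2 vector or n x 2 matrix of pixel coordinates.
#' @param h 3 x 3 homography matrix.
#' @return transformed coordinates, same shape as the input.
#' @examples
#' applyHomography(c(10, 20), diag(3))
#' @export
applyHomography <- function(pts, h) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L, 2L) else as.matrix(pts)
  q <- cbind(p, 1) %*% t(h)
  w <- q[, 3]
  if (any(abs(w) < 1e-12)) stop("point at infinity")
  out <- q[, 1:2, drop = FALSE] / w
  if (vec) as.numeric(out) else out
}

#' Radial lens distortion model
#'
#' Two-coefficient radial model around a principal point: a point at
#' normalized distorted radius r maps to corrected radius
#' r (1 + k1 r^2 + k2 r^4), with radii normalized by the focal length f.
#'
#' @param k1,k2 radial distortion coefficients.
#' @param cx,cy principal point (pixels).
#' @param f focal length (pixels), > 0.
#' @return a `DistortionModel` list.
#' @export
distortionModel <- function(k1 = 0, k2 = 0, cx, cy, f) {
  stopifnot(f > 0)
  structure(list(k1 = k1, k2 = k2, cx = cx, cy = cy, f = f),
            class = "DistortionModel")
}

# corrected radius as a function of distorted radius (normalized units)
.radialForward <- function(r, m) r * (1 + m$k1 * r^2 + m$k2 * r^4)

# invert the radial model by Newton iteration (vectorized)
.radialInverse <- function(rc, m, iter = 25L) {
  r <- rc
  for (i in seq_len(iter)) {
    f <- r * (1 + m$k1 * r^2 + m$k2 * r^4) - rc
    fp <- 1 + 3 * m$k1 * r^2 + 5 * m$k2 * r^4
    r <- r - f / fp
  }
  r
}

#' Undistort (or distort) points
#'
#' `undistortPoints` maps distorted pixel coordinates to corrected ones with
#' the closed-form radial model; `distortPoints` is its Newton-iterated
#' inverse.
#'
#' @param pts n x 2 matrix or length-2 vector of pixel coordinates.
#' @param model a [distortionModel()].
#' @return coordinates of the same shape.
#' @export
undistortPoints <- function(pts, model) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L, 2L) else as.matrix(pts)
  xn <- (p[, 1] - model$cx) / model$f
  yn <- (p[, 2] - model$cy) / model$f
  r <- sqrt(xn^2 + yn^2)
  scale <- ifelse(r > 0, .radialForward(r, model) / r, 1)
  out <- cbind(model$cx + xn * scale * model$f,
               model$cy + yn * scale * model$f)
  if (vec) as.numeric(out) else out
}

#' @rdname undistortPoints
#' @export
distortPoints <- function(pts, model) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L, 2L) else as.matrix(pts)
  xn <- (p[, 1] - model$cx) / model$f
  yn <- (p[, 2] - model$cy) / model$f
  rc <- sqrt(xn^2 + yn^2)
  rd <- .radialInverse(rc, model)
  scale <- ifelse(rc > 0, rd / rc, 1)
  out <- cbind(model$cx + xn * scale * model$f,
               model$cy + yn * scale * model$f)
  if (vec) as.numeric(out) else out
}

#' Undistort an image
#'
#' Produces the corrected image by backward warping: each corrected output
#' pixel samples the input at the distorted position obtained by inverting
#' the radial model (Newton iteration), with bilinear interpolation.
#' Output dimensions equal input dimensions.
#'
#' @param frame an [ArenaFrame-class].
#' @param model a [distortionModel()].
#' @param interpolation "bilinear" or "nearest".
#' @return an undistorted ArenaFrame.
#' @export
undistortImage <- function(frame, model,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  px <- pixels(frame)
  if (model$k1 == 0 && model$k2 == 0) return(frame)
  H <- dim(px)[1]; W <- dim(px)[2]
  g <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  srcPts <- distortPoints(cbind(g$x, g$y), model)
  sampler <- if (interpolation == "bilinear") .bilinearSample else .nearestSample
  vals <- sampler(px, srcPts[, 1], srcPts[, 2])
  vals[is.na(vals)] <- 0
  out <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(vals[, ch], H, W, byrow = TRUE)
  frame@pixels <- .clip255(out)
  frame
}

#' Apply lens distortion to an image (synthetic-test utility)
#'
#' Forward counterpart of [undistortImage()]: renders the distorted image
#' from an ideal one, so that distort-then-undistort round trips can be
#' verified on synthetic scenes.
#'
#' @inheritParams undistortImage
#' @return a distorted ArenaFrame.
#' @export
distortImage <- function(frame, model,
                         interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  px <- pixels(frame)
  if (model$k1 == 0 && model$k2 == 0) return(frame)
  H <- dim(px)[1]; W <- dim(px)[2]
  g <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  srcPts <- undistortPoints(cbind(g$x, g$y), model)
  sampler <- if (interpolation == "bilinear") .bilinearSample else .nearestSample
  vals <- sampler(px, srcPts[, 1], srcPts[, 2])
  vals[is.na(vals)] <- 0
  out <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(vals[, ch], H, W, byrow = TRUE)
  frame@pixels <- .clip255(out)
  frame
}

#' Stitch two views along a hard stitch line
#'
#' Composites two luminosity-compensated views into one large image. The
#' composite covers the joint bounding box of image A's corners and image B's
#' corners warped by `h` (which maps B coordinates into A's frame). Every
#' composite pixel originates from exactly one source image, decided by a
#' stitch line -- there is no blending. The default stitch line is the
#' perpendicular bisector of the segment joining the two image centres in
#' composite coordinates; any polyline (m x 2 matrix in A-frame coordinates)
#' may be supplied instead, pixels being attributed by the side of their
#' nearest polyline segment.
#'
#' @param frameA,frameB [ArenaFrame-class] views.
#' @param h 3 x 3 homography mapping B pixel coordinates into A's frame.
#' @param line optional polyline (m x 2 matrix, A-frame coordinates).
#' @param interpolation "bilinear" (default) or "nearest" for sampling B.
#' @return a list with `composite` (ArenaFrame), `origin` (A-frame
#'   coordinates of the composite's top-left pixel) and `fromA` (logical
#'   matrix marking which composite pixels came from A).
#' @export
stitchImages <- function(frameA, frameB, h, line = NULL,
                         interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  pa <- pixels(frameA); pb <- pixels(frameB)
  Ha <- dim(pa)[1]; Wa <- dim(pa)[2]
  Hb <- dim(pb)[1]; Wb <- dim(pb)[2]
  cornersA <- cbind(c(0, Wa - 1, 0, Wa - 1), c(0, 0, Ha - 1, Ha - 1))
  cornersB <- applyHomography(
    cbind(c(0, Wb - 1, 0, Wb - 1), c(0, 0, Hb - 1, Hb - 1)), h)
  xmin <- floor(min(cornersA[, 1], cornersB[, 1]))
  ymin <- floor(min(cornersA[, 2], cornersB[, 2]))
  xmax <- ceiling(max(cornersA[, 1], cornersB[, 1]))
  ymax <- ceiling(max(cornersA[, 2], cornersB[, 2]))
  Wc <- xmax - xmin + 1L; Hc <- ymax - ymin + 1L

  # composite pixel grid expressed in A-frame coordinates
  gx <- rep(xmin:xmax, each = Hc)
  gy <- rep(ymin:ymax, times = Wc)
  inA <- gx >= 0 & gx <= Wa - 1 & gy >= 0 & gy <= Ha - 1
  hinv <- solve(h)
  bpts <- applyHomography(cbind(gx, gy), hinv)
  inB <- bpts[, 1] >= -0.5 & bpts[, 1] <= Wb - 0.5 &
         bpts[, 2] >= -0.5 & bpts[, 2] <= Hb - 0.5
  if (!any(inA & inB)) stop("no overlap")

  centreA <- c((Wa - 1) / 2, (Ha - 1) / 2)
  centreB <- applyHomography(c((Wb - 1) / 2, (Hb - 1) / 2), h)
  if (is.null(line)) {
    mid <- (centreA + centreB) / 2
    dir <- centreA - centreB
    sideA <- (gx - mid[1]) * dir[1] + (gy - mid[2]) * dir[2] > 0
  } else {
    line <- as.matrix(line)
    sideA <- .polylineSide(cbind(gx, gy), line, centreA)
  }

  useA <- (sideA & inA) | (inA & !inB)
  useB <- !useA & inB

  vals <- matrix(0, length(gx), 3L)
  if (any(useA)) {
    for (ch in 1:3) {
      base <- (ch - 1L) * Ha * Wa
      vals[useA, ch] <- pa[base + gy[useA] + 1L + Ha * gx[useA]]
    }
  }
  if (any(useB)) {
    sampler <- if (interpolation == "bilinear") .bilinearSample else .nearestSample
    sb <- sampler(pb, bpts[useB, 1], bpts[useB, 2])
    sb[is.na(sb)] <- 0
    vals[useB, ] <- sb
  }
  comp <- array(0, dim = c(Hc, Wc, 3L))
  for (ch in 1:3) comp[, , ch] <- matrix(vals[, ch], Hc, Wc)
  res <- arenaFrame(.clip255(comp), resolution = resolution(frameA),
                    timestamp = timestamp(frameA), cameraId = "composite")
  list(composite = res, origin = c(xmin, ymin),
       fromA = matrix(useA, Hc, Wc))
}

# Which side of a polyline a set of points falls on, TRUE meaning the same
# side as the reference point; each point is classified against its nearest
# polyline segment.
.polylineSide <- function(pts, line, ref) {
  nseg <- nrow(line) - 1L
  signedNearest <- function(p) {
    best <- Inf; sgn <- 1
    for (i in seq_len(nseg)) {
      a <- line[i, ]; b <- line[i + 1L, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      q <- a + t * ab
      d2 <- sum((p - q)^2)
      if (d2 < best) {
        best <- d2
        sgn <- sign(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1]))
      }
    }
    sgn
  }
  refSign <- signedNearest(ref)
  if (nseg == 1L) {
    a <- line[1, ]; ab <- line[2, ] - a
    s <- sign(ab[1] * (pts[, 2] - a[2]) - ab[2] * (pts[, 1] - a[1]))
    return(s == refSign)
  }
  apply(pts, 1L, function(p) signedNearest(p) == refSign)
}

#' Default stitch line between two views
#'
#' The perpendicular bisector of the segment joining image A's centre and
#' image B's warped centre, returned as a two-point polyline in A-frame
#' coordinates (long enough to span any composite).
#'
#' @inheritParams stitchImages
#' @return 2 x 2 matrix polyline.
#' @export
defaultStitchLine <- function(frameA, frameB, h) {
  pa <- pixels(frameA); pb <- pixels(frameB)
  centreA <- c((dim(pa)[2] - 1) / 2, (dim(pa)[1] - 1) / 2)
  centreB <- applyHomography(c((dim(pb)[2] - 1) / 2, (dim(pb)[1] - 1) / 2), h)
  mid <- (centreA + centreB) / 2
  dir <- centreA - centreB
  perp <- c(-dir[2], dir[1])
  L <- 4 * (sum(dim(pa)[1:2]) + sum(dim(pb)[1:2]))
  perp <- perp / sqrt(sum(perp^2)) * L
  rbind(mid - perp, mid + perp)
}
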
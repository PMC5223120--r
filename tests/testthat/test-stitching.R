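test_that("luminosity compensation equalizes means and preserves structure", {
  a <- arenaFrame(array(100, dim = c(8, 8, 3)))
  b <- arenaFrame(array(120, dim = c(8, 8, 3)))
  out <- compensateLuminosity(list(a, b))
  expect_equal(mean(luminance(pixels(out[[1]]))), 110, tolerance = 1e-12)
  expect_equal(mean(luminance(pixels(out[[2]]))), 110, tolerance = 1e-12)

  # identical images and single images are returned unchanged
  out2 <- compensateLuminosity(list(a, a))
  expect_identical(pixels(out2[[1]]), pixels(a))
  out3 <- compensateLuminosity(list(b))
  expect_identical(pixels(out3[[1]]), pixels(b))

  expect_error(compensateLuminosity(list()), "no images")

  # pure offset: dimensions unchanged, contrast ordering preserved
  set.seed(11)
  m1 <- matrix(runif(100, 40, 210), 10, 10)
  f1 <- arenaFrame(m1)
  f2 <- arenaFrame(matrix(150, 10, 10))
  cc <- compensateLuminosity(list(f1, f2))
  expect_equal(dim(pixels(cc[[1]])), dim(pixels(f1)))
  expect_identical(order(luminance(pixels(cc[[1]]))), order(m1))
})

test_that("homography estimation recovers exact and noisy transforms", {
  # identity and pure translation from 4 pairs
  src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  expect_equal(estimateHomography(src, src), diag(3), tolerance = 1e-9)
  Ht <- estimateHomography(src, src + rep(c(5, -3), each = 4))
  expect_equal(Ht, rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1)),
               tolerance = 1e-9)

  # noise-free projective recovery to 1e-6 relative error
  set.seed(4)
  H <- rbind(c(1.05, 0.04, 22), c(-0.03, 0.97, -11), c(2e-5, -1e-5, 1))
  pts <- cbind(runif(12, 0, 600), runif(12, 0, 400))
  dst <- applyHomography(pts, H)
  Hh <- estimateHomography(pts, dst)
  expect_lt(max(abs(Hh - H)) / max(abs(H)), 1e-6)

  # gaussian pixel noise sigma = 0.2 -> mean reprojection error <= 0.5 px
  dstn <- dst + matrix(rnorm(24, 0, 0.2), ncol = 2)
  Hn <- estimateHomography(pts, dstn)
  err <- sqrt(rowSums((applyHomography(pts, Hn) - dstn)^2))
  expect_lte(mean(err), 0.5)

  expect_error(estimateHomography(src[1:3, ], src[1:3, ]),
               "insufficient correspondences")
  col <- cbind(1:6, 2 * (1:6))  # all source points collinear
  expect_error(estimateHomography(col, col + 1),
               "insufficient correspondences")
})

test_that("homography application follows projective arithmetic", {
  expect_equal(applyHomography(c(10, 20), diag(3)), c(10, 20))
  Ht <- rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1))
  expect_equal(applyHomography(c(0, 0), Ht), c(5, -3))
  # round trip through the inverse
  H <- rbind(c(1.1, 0.1, 3), c(0, 0.9, -2), c(1e-4, 0, 1))
  p <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  expect_equal(applyHomography(applyHomography(p, H), solve(H)), p,
               tolerance = 1e-9)
  # point mapped to infinity
  Hbad <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 1))
  expect_error(applyHomography(c(1, 5), Hbad), "point at infinity")
})

test_that("radial undistortion inverts the lens model", {
  truth <- sceneTruth(arenaRadiusCm = 8, noiseSigma = 0)
  f <- renderFrame(truth, 1)
  ident <- distortionModel(0, 0, cx = 100, cy = 100, f = 300)
  expect_identical(pixels(undistortImage(f, ident)), pixels(f))

  m <- distortionModel(k1 = 0.08, k2 = -0.015, cx = 120, cy = 118, f = 350)
  # distort-then-undistort round trip on interior points
  set.seed(2)
  pts <- cbind(runif(200, 30, 200), runif(200, 30, 200))
  rt <- undistortPoints(distortPoints(pts, m), m)
  expect_lt(max(sqrt(rowSums((rt - pts)^2))), 0.5)

  # straight lines distorted with a known model come back collinear
  grid <- expand.grid(x = seq(40, 200, by = 20), y = seq(40, 200, by = 20))
  bent <- distortPoints(as.matrix(grid), m)
  straight <- undistortPoints(bent, m)
  for (yv in unique(grid$y)) {
    row <- straight[grid$y == yv, ]
    fit <- stats::lm(row[, 2] ~ row[, 1])
    expect_lt(max(abs(stats::resid(fit))), 0.5)
  }
  expect_equal(dim(pixels(undistortImage(f, m))), dim(pixels(f)))
})

test_that("hard stitch line composites each pixel from exactly one source", {
  # two views of a uniform grey field -> uniform composite
  a <- arenaFrame(array(120, dim = c(40, 60, 3)))
  b <- arenaFrame(array(120, dim = c(40, 60, 3)))
  h <- rbind(c(1, 0, 30), c(0, 1, 0), c(0, 0, 1))
  st <- stitchImages(a, b, h)
  expect_equal(unique(as.vector(pixels(st$composite))), 120)
  expect_equal(dim(pixels(st$composite))[1:2], c(40, 90))

  # pure translation: composite equals the union of the two images,
  # each side of the line coming from its designated source
  pa <- array(80, dim = c(20, 30, 3)); pa[5, 3, ] <- 10
  pb <- array(80, dim = c(20, 30, 3)); pb[15, 28, ] <- 20
  st2 <- stitchImages(arenaFrame(pa), arenaFrame(pb),
                      rbind(c(1, 0, 15), c(0, 1, 0), c(0, 0, 1)))
  comp <- pixels(st2$composite)
  expect_equal(comp[5, 3, 1], 10)    # from A (left of the line)
  expect_equal(comp[15, 43, 1], 20)  # from B, shifted by 15
  expect_true(all(st2$fromA[, 1:10]))
  expect_true(!any(st2$fromA[, 36:45]))

  expect_error(
    stitchImages(a, b, rbind(c(1, 0, 1000), c(0, 1, 0), c(0, 0, 1))),
    "no overlap")
})

test_that("a seed in the overlap region appears exactly once after stitching", {
  truth <- sceneTruth(
    seeds = data.frame(x_cm = 0.1, y_cm = -0.2, width_mm = 2),
    arenaRadiusCm = 4, noiseSigma = 0)
  pair <- renderFrame(truth, 1, view = "two")
  st <- stitchImages(pair$a, pair$b, pair$h)
  params <- segmentationParams()
  mask <- luminance(pixels(st$composite)) <= params@darkThreshold
  blobs <- detectBlobs(mask, params)
  expect_equal(nrow(blobs), 1L)
  expect_gte(blobs$size_px, params@seedMinPx)
})
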
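test_that("modal background takes the per-pixel majority triplet", {
  mk <- function(rgb, H = 4, W = 4) {
    a <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) a[, , ch] <- rgb[ch]
    arenaFrame(a)
  }
  # constant pixel
  bg <- buildBackground(rep(list(mk(c(50, 50, 50))), 15))
  expect_true(all(pixels(bg) == 50))
  # 10 frames (10,10,10) vs 5 frames (200,0,0)
  frames <- c(rep(list(mk(c(10, 10, 10))), 10), rep(list(mk(c(200, 0, 0))), 5))
  bg2 <- buildBackground(frames)
  expect_equal(pixels(bg2)[1, 1, ], c(10, 10, 10))
  # 7-7 tie (plus one other): lexicographically smallest triplet wins
  frames3 <- c(rep(list(mk(c(10, 10, 10))), 7), rep(list(mk(c(200, 0, 0))), 7),
               list(mk(c(90, 90, 90))))
  bg3 <- buildBackground(frames3)
  expect_equal(pixels(bg3)[1, 1, ], c(10, 10, 10))

  expect_error(buildBackground(list(mk(c(1, 1, 1)))), "at least 2")
  expect_error(buildBackground(list(mk(c(1, 1, 1)), mk(c(1, 1, 1), H = 5))),
               "mismatch")

  # manual patches overwrite regions
  bg4 <- buildBackground(frames, manualPatches = list(
    list(region = c(0, 0, 1, 1), rgb = c(7, 8, 9))))
  expect_equal(pixels(bg4)[1, 1, ], c(7, 8, 9))
  expect_equal(pixels(bg4)[3, 3, ], c(10, 10, 10))
})

test_that("difference segmentation uses strict Euclidean RGB threshold", {
  base <- greyFrame(6, 6, level = 100)
  bg <- buildBackground(list(base, base))
  params <- segmentationParams(diffThreshold = 20)
  expect_false(any(segmentDifference(base, bg, params)))

  px <- pixels(base)
  px[3, 4, 1] <- 130  # +30 in red only
  f <- arenaFrame(px)
  m <- segmentDifference(f, bg, params)
  expect_identical(which(m), which(matrix(seq_len(36), 6, 6) == 3 + 6 * 3))
  expect_equal(sum(m), 1L)

  # exactly at the threshold: excluded
  px2 <- pixels(base); px2[2, 2, 1] <- 120
  expect_false(any(segmentDifference(arenaFrame(px2), bg, params)))
  expect_error(segmentDifference(greyFrame(5, 6), bg, params), "dimensions")
})

test_that("darkness segmentation keeps only dark pixels of the mask", {
  params <- segmentationParams(darkThreshold = 80)
  white <- greyFrame(4, 4, level = 255)
  allMask <- matrix(TRUE, 4, 4)
  expect_false(any(segmentDark(white, allMask, params)))

  dark <- greyFrame(4, 4, level = 255, patches = list(c(1, 1, 2, 2, 30)))
  m <- segmentDark(dark, allMask, params)
  expect_equal(sum(m), 4L)
  expect_false(any(segmentDark(dark, matrix(FALSE, 4, 4), params)))
})

test_that("persistence filter implements the full 2-of-3 truth table", {
  combos <- expand.grid(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  masks <- lapply(c("a", "b", "c"), function(k)
    matrix(as.logical(combos[[k]]), nrow(combos), 1))
  out <- persistenceFilter(masks)
  expect_equal(as.vector(out), rowSums(combos) >= 2)
  expect_error(persistenceFilter(masks[1:2]), "3")
})

test_that("blob detection respects connectivity and computes centroids", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2:6] <- TRUE; m[3, 2:6] <- TRUE  # 10 contiguous pixels
  b <- detectBlobs(m, segmentationParams())
  expect_equal(nrow(b), 1L)
  expect_equal(b$size_px, 10L)
  expect_equal(b$x_px, mean(1:5))  # 0-based centroid
  expect_equal(b$y_px, 1.5)

  expect_equal(nrow(detectBlobs(matrix(FALSE, 4, 4), segmentationParams())),
               0L)

  # diagonal touching: 2 blobs at connectivity 4, 1 at connectivity 8
  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nrow(detectBlobs(d, segmentationParams(connectivity = 4))), 2L)
  expect_equal(nrow(detectBlobs(d, segmentationParams(connectivity = 8))), 1L)
})

test_that("component labeling agrees with independent oracles on random masks", {
  set.seed(42)
  for (i in 1:8) {
    m <- matrix(runif(48 * 48) < 0.35, 48, 48)
    lab8 <- labelComponents(m, 8L)
    expect_identical(labelPartition(lab8), labelPartition(bfsLabel(m, 8L)))
    lab4 <- labelComponents(m, 4L)
    expect_identical(labelPartition(lab4), labelPartition(bfsLabel(m, 4L)))
    if (requireNamespace("EBImage", quietly = TRUE)) {
      # EBImage::bwlabel is 4-connected
      ref <- EBImage::bwlabel(m * 1L)
      expect_identical(labelPartition(lab4), labelPartition(ref))
    }
  }
})

test_that("size gate classifies persistent blobs and never double-assigns", {
  params <- segmentationParams()
  persistent <- matrix(FALSE, 20, 40)
  persistent[3:4, 3:7] <- TRUE       # 10 px -> seed
  persistent[10:14, 10:14] <- TRUE   # 25 px -> discarded (static ant)
  moving <- persistent
  moving[16:18, 25:34] <- TRUE       # 30 px non-persistent -> ant
  fd <- classifyFrame(persistent, moving, params, resolution = 0.677,
                      nestCentre = c(20, 10))
  expect_equal(nrow(seeds(fd)), 1L)
  expect_equal(seeds(fd)$size_px, 10L)
  expect_equal(nrow(fd@discarded), 1L)
  expect_equal(fd@discarded$size_px, 25L)
  expect_equal(nrow(ants(fd)), 1L)
  expect_equal(ants(fd)$size_px, 30L)
  # no pixel of the persistent mask can reach the ant class
  expect_false(any(ants(fd)$x_px %in% seeds(fd)$x_px &
                   ants(fd)$y_px %in% seeds(fd)$y_px))
})

test_that("pixel/arena coordinate conversion is exact and invertible", {
  expect_equal(pxToCm(c(50, 60), 0.677, c(50, 60)), c(0, 0))
  expect_equal(pxToCm(c(150, 60), 0.677, c(50, 60)), c(6.77, 0))
  # y axis flips so arena y points up
  expect_equal(pxToCm(c(50, 0), 1, c(50, 60)), c(0, 6))
  set.seed(5)
  p <- cbind(runif(30, -50, 50), runif(30, -50, 50))
  expect_equal(pxToCm(cmToPx(p, 0.677, c(300, 300)), 0.677, c(300, 300)), p,
               tolerance = 1e-9)
})

test_that("noise-free pipeline recovers the exact ground-truth seed count", {
  truth <- randomScene(12, arenaRadiusCm = 6, noiseSigma = 0, seedAppear = 3,
                       seed = 3)
  frames <- lapply(1:5, function(f) renderFrame(truth, f))
  bg <- buildBackground(frames[1:2])
  det <- detectSequence(frames[3:5], bg, nestCentre = sceneNestCentre(truth))
  expect_equal(nrow(seeds(det[[2]])), 12L)
  expect_equal(nrow(ants(det[[2]])), 0L)
})

test_that("detected seed count is invariant to global luminance offsets", {
  truth <- randomScene(10, arenaRadiusCm = 6, noiseSigma = 3, seedAppear = 3,
                       seed = 8)
  frames <- lapply(1:5, function(f) renderFrame(truth, f))
  counts <- vapply(c(-20, 0, 20), function(off) {
    shifted <- lapply(frames, function(f) {
      f@pixels <- pmin(pmax(pixels(f) + off, 0), 255); f
    })
    comp <- compensateLuminosity(shifted)
    bg <- buildBackground(comp[1:2])
    det <- detectSequence(comp[3:5], bg, nestCentre = sceneNestCentre(truth))
    nrow(seeds(det[[2]]))
  }, integer(1))
  expect_true(all(counts == counts[1]))
  expect_equal(counts[1], 10L)
})
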
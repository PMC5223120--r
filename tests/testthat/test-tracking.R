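test_that("episode linking follows the match-radius rule", {
  # a seed at a fixed pixel over frames 3..8 -> one episode of 6 frames
  det <- c(lapply(1:2, function(f) makeDetections(f, numeric())),
           lapply(3:8, function(f) makeDetections(f, 100)))
  eps <- linkEpisodes(det, dt = 10)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$first_frame, 3)
  expect_equal(eps$last_frame, 8)
  expect_equal(eps$duration_min, 60)

  # 1 px jitter within a 3 px radius stays one episode
  jit <- lapply(1:6, function(f) makeDetections(f, 100 + (f %% 2)))
  expect_equal(nrow(linkEpisodes(jit, matchRadiusPx = 3, dt = 10)), 1L)

  # a 50 px jump closes the first episode and opens a second
  jump <- c(lapply(1:5, function(f) makeDetections(f, 100)),
            lapply(6:9, function(f) makeDetections(f, 150)))
  eps2 <- linkEpisodes(jump, dt = 10)
  expect_equal(nrow(eps2), 2L)
  expect_equal(eps2$last_frame[1], 5)
  expect_equal(eps2$first_frame[2], 6)

  expect_error(linkEpisodes(rev(det)), "ordered")
})

test_that("no detection is lost or double-assigned during linking", {
  set.seed(31)
  for (trial in 1:5) {
    det <- lapply(1:12, function(f) {
      n <- sample(0:6, 1)
      makeDetections(f, xs = runif(n, 0, 500) , ys = runif(n, 0, 500))
    })
    eps <- linkEpisodes(det, matchRadiusPx = 3, dt = 10)
    nDet <- sum(vapply(det, function(d) nrow(seeds(d)), integer(1)))
    expect_equal(sum(eps$n_frames), nDet)
  }
})

test_that("scheduled appear/disappear scenes are recovered exactly", {
  # schedule: seed A frames 1..4 at x=100; seed B frames 5..9 at x=400;
  # seed C frames 2..9 at x=250
  sched <- list(A = list(f = 1:4, x = 100), B = list(f = 5:9, x = 400),
                C = list(f = 2:9, x = 250))
  det <- lapply(1:9, function(f) {
    xs <- unlist(lapply(sched, function(s) if (f %in% s$f) s$x else NULL))
    makeDetections(f, xs)
  })
  eps <- linkEpisodes(det, dt = 10)
  eps <- eps[order(eps$x_px), ]
  expect_equal(eps$first_frame, c(1, 2, 5))
  expect_equal(eps$last_frame, c(4, 9, 9))
  expect_equal(eps$duration_min, c(40, 80, 50))
})

test_that("redispersal distance is the nearest new episode within 2 frames", {
  # closing episode at (0,0); new episodes at (3,4) and (6,8) cm next frame
  resolution <- 10  # 1 px = 1 cm for readability
  det <- list(
    makeDetections(1, 0, 0, resolution = resolution),
    makeDetections(2, 0, 0, resolution = resolution),
    makeDetections(3, c(3, 6), c(-4, -8), resolution = resolution),
    makeDetections(4, c(3, 6), c(-4, -8), resolution = resolution))
  eps <- redispersalDistances(linkEpisodes(det, dt = 10))
  closing <- eps[eps$last_frame == 2, ]
  expect_equal(closing$redisp_dist_cm, 5)

  # no new episode within the window -> undefined (NA), never zero
  det2 <- list(makeDetections(1, 0), makeDetections(2, 0),
               makeDetections(3, numeric()), makeDetections(4, numeric()),
               makeDetections(5, numeric()), makeDetections(6, 500))
  eps2 <- redispersalDistances(linkEpisodes(det2, dt = 10))
  expect_true(is.na(eps2$redisp_dist_cm[eps2$last_frame == 2]))

  # appearing exactly 3 frames later is outside the 2-frame window
  det3 <- list(makeDetections(1, 0), makeDetections(2, 0),
               makeDetections(3, numeric()), makeDetections(4, numeric()),
               makeDetections(5, 30))
  eps3 <- redispersalDistances(linkEpisodes(det3, dt = 10))
  expect_true(is.na(eps3$redisp_dist_cm[eps3$last_frame == 2]))
  expect_true(all(stats::na.omit(eps3$redisp_dist_cm) >= 0))
})

test_that("rejection dynamics count open episodes per frame", {
  expect_equal(rejectionDynamics(
    linkEpisodes(list(makeDetections(1, numeric()),
                      makeDetections(2, numeric())), dt = 10),
    1:2)$n_seeds, c(0L, 0L))

  # staircase: one new eternal episode per frame
  det <- lapply(1:6, function(f) makeDetections(f, seq(0, by = 100,
                                                       length.out = f)))
  eps <- linkEpisodes(det, dt = 10)
  rd <- rejectionDynamics(eps, 1:6, sCountEnd = 6)
  expect_equal(rd$n_seeds, 1:6)
  expect_equal(rd$eta_rejected, (1:6) / 6)
  expect_equal(attr(rd, "S_track_end"), 6L)
  expect_error(rejectionDynamics(eps, 1:6, sCountEnd = 0), "positive")
})

test_that("episodes spanning a night gap are flagged", {
  det <- lapply(1:6, function(f) makeDetections(f, 100,
                                                timestamp = ifelse(f <= 3, f * 10, 600 + f * 10)))
  eps <- linkEpisodes(det, dt = 10)
  expect_equal(nrow(eps), 1L)
  expect_true(eps$gap)
  detNoGap <- lapply(1:6, function(f) makeDetections(f, 100))
  expect_false(linkEpisodes(detNoGap, dt = 10)$gap)
})
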
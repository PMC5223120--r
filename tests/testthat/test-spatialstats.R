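test_that("area of interest shrinks the disc by the border buffer", {
  expect_equal(areaOfInterest(discRegion(c(0, 0), 200), 5)$radius, 195)
  reg <- discRegion(c(1, 2), 50)
  expect_identical(areaOfInterest(reg, 0), reg)
  expect_error(areaOfInterest(reg, 50), "smaller")
})

test_that("nearest-neighbour distances match elementary cases and brute force", {
  two <- cbind(c(0, 5), c(0, 0))
  expect_equal(nnDistances(two), c(5, 5))
  colin <- cbind(c(0, 1, 3), c(0, 0, 0))
  expect_equal(nnDistances(colin), c(1, 1, 2))
  dup <- cbind(c(2, 2, 9), c(3, 3, 9))
  expect_equal(nnDistances(dup)[1:2], c(0, 0))
  expect_error(nnDistances(cbind(1, 1)), ">=2")

  set.seed(7)
  xy <- cbind(runif(400, 0, 10), runif(400, 0, 10))
  dm <- as.matrix(stats::dist(xy)); diag(dm) <- Inf
  expect_equal(nnDistances(xy), unname(apply(dm, 1, min)), tolerance = 1e-12)
})

test_that("G-function is a valid CDF estimate matching the Poisson law", {
  reg <- discRegion(c(0, 0), 50)
  p2 <- pointPattern(cbind(c(0, 5), c(0, 0)), reg)
  g <- gFunction(p2, dGrid = c(4.9, 5, 6))
  expect_equal(g$G, c(0, 1, 1))

  set.seed(12)
  pat <- simulateCSR(500, reg, seed = 9)
  gc <- gFunction(pat)
  expect_true(all(diff(gc$G) >= 0))
  expect_true(all(gc$G >= 0 & gc$G <= 1))

  # closed-form CSR nearest-neighbour law, G(d) = 1 - exp(-rho pi d^2)
  sq <- polygonRegion(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  big <- simulateCSR(10000, sq, seed = 42)
  gg <- gFunction(big, dGrid = seq(0, 2, length.out = 256))
  expect_lte(max(abs(gg$G - (1 - exp(-pi * gg$d^2)))), 0.02)
})

test_that("CSR simulation is uniform with the expected NN scale", {
  reg <- discRegion(c(3, -2), 40)
  expect_equal(nPoints(simulateCSR(0, reg, seed = 1)), 0L)
  p <- simulateCSR(300, reg, seed = 2)
  expect_true(all(regionContains(reg, coords(p))))
  # mean NN distance over many draws ~ 1/(2 sqrt(rho)) within 3%
  n <- 200
  mn <- mean(vapply(1:80, function(i)
    mean(nnDistances(simulateCSR(n, reg, seed = 100 + i))), numeric(1)))
  expect_lt(abs(mn - 0.5 / sqrt(n / regionArea(reg))) /
              (0.5 / sqrt(n / regionArea(reg))), 0.03)
  # polygon sampling stays inside
  tri <- polygonRegion(rbind(c(0, 0), c(10, 0), c(5, 8)))
  pt <- simulateCSR(150, tri, seed = 3)
  expect_true(all(regionContains(tri, coords(pt))))
})

test_that("envelope bounds order and degenerate nSim behave", {
  pat <- simulateCSR(40, discRegion(c(0, 0), 50), seed = 4)
  env <- csrEnvelope(pat, nSim = 25, seed = 5)
  expect_true(all(env@lo <= env@simMean + 1e-12))
  expect_true(all(env@simMean <= env@hi + 1e-12))
  env1 <- csrEnvelope(pat, nSim = 1, seed = 6)
  expect_equal(env1@lo, env1@hi)
  expect_equal(env1@lo, as.vector(env1@simCurves[1, ]))
})

test_that("a CSR pattern usually stays inside a 999-simulation envelope", {
  # min/max envelopes of few simulations have a high global excursion
  # probability (each grid point is a 1/(nSim+1) event but many are probed),
  # so global containment needs the paper-scale simulation count
  reg <- discRegion(c(0, 0), 100)
  inside <- vapply(1:30, function(i) {
    obs <- simulateCSR(100, reg, seed = 700 + i)
    env <- csrEnvelope(obs, nSim = 999, seed = 800 + i)
    all(env@obs >= env@lo & env@obs <= env@hi)
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("DCLF statistic, rank convention and verdicts are coherent", {
  pat <- simulateCSR(50, discRegion(c(0, 0), 100), seed = 20)
  env <- csrEnvelope(pat, nSim = 99, seed = 21)
  # observed curve replaced by the simulation mean -> u_obs = 0, p near 1
  env2 <- env
  env2@obs <- env@simMean
  d2 <- dclfTest(env2)
  expect_equal(d2@uObs, 0)
  expect_gt(d2@p, 0.5)
  expect_error(dclfTest(env, dMax = 1e6), "outside")

  # strongly clustered pattern: most extreme among its simulations
  thom <- simulateThomas(20, 10, 3, discRegion(c(0, 0), 195), seed = 22)
  envT <- csrEnvelope(thom, nSim = 99, seed = 23)
  dT <- dclfTest(envT)
  expect_equal(dT@rank, 1L)
  expect_equal(dT@p, 1 / 100)
  expect_equal(dT@verdict, "clustered")
})

test_that("characteristic distances isolate the clustered fraction", {
  pat <- simulateCSR(50, discRegion(c(0, 0), 100), seed = 30)
  env <- csrEnvelope(pat, nSim = 99, seed = 31)
  # never above the upper bound -> f_star 0, empty summaries
  env@obs <- env@lo
  cd0 <- characteristicDistances(env)
  expect_equal(cd0$f_star, 0)
  expect_equal(unname(cd0$nndist_cluster["n"]), 0)

  # above the bound everywhere -> f_star 1, summaries over all distances
  envAll <- csrEnvelope(pat, nSim = 99, seed = 31)
  envAll@obs <- rep(1, length(envAll@dGrid))  # above hi wherever hi < 1
  cd1 <- characteristicDistances(envAll)
  expect_equal(cd1$f_star, 1)
  expect_equal(unname(cd1$nndist_cluster["n"]), length(envAll@obsNN))

  # two tight clusters in a large disc: cluster distance far below CSR's
  reg <- discRegion(c(0, 0), 195)
  cl <- rbind(
    cbind(80 + c(0, 1, 0, 1, 0.5), 10 + c(0, 0, 1, 1, 0.5)),
    cbind(-60 + c(0, 1, 0, 1, 0.5), -90 + c(0, 0, 1, 1, 0.5)))
  patC <- pointPattern(cl, reg)
  envC <- csrEnvelope(patC, nSim = 199, seed = 32)
  dC <- dclfTest(envC)
  cdC <- characteristicDistances(envC, dC)
  expect_equal(dC@verdict, "clustered")
  expect_lte(unname(cdC$nndist_cluster["median"]), 2)
  expect_lt(cdC$nndist_cluster["median"], cdC$nndist_csr["median"])

  # a non-clustered verdict yields the empty result by contract
  dCSR <- new("DCLFResult", uObs = 0, uSim = 0, rank = 50L, p = 0.5,
              verdict = "CSR", alternative = "upper", dMax = 1)
  expect_equal(characteristicDistances(envC, dCSR)$f_star, 0)
})

test_that("radial density divides ring counts by clipped ring areas", {
  reg <- discRegion(c(0, 0), 25)
  inner <- pointPattern(cbind(runif(20, -5, 5), runif(20, -5, 5)), reg)
  rd <- radialDensity(inner, ringWidth = 10)
  expect_equal(rd$count[1], 20)
  expect_equal(rd$density[1], 20 / (pi * 100))
  expect_equal(rd$outer[length(rd$outer)], 25)  # clipped at the region

  empty <- pointPattern(matrix(numeric(), 0, 2), reg)
  expect_true(all(radialDensity(empty)$density == 0))

  # uniform pattern -> roughly constant density across rings
  u <- simulateCSR(4000, reg, seed = 40)
  rdu <- radialDensity(u, ringWidth = 5)
  rho <- 4000 / regionArea(reg)
  expect_true(all(abs(rdu$density - rho) / rho < 0.2))
})

test_that("distance summary quartiles match a sort-based oracle", {
  expect_equal(unname(distanceSummary(cbind(c(1, 2, 3), 0))["median"]), 2)
  one <- distanceSummary(cbind(7, 0))
  expect_equal(unname(one[c("median", "q1", "q3")]), c(7, 7, 7))
  expect_error(distanceSummary(matrix(numeric(), 0, 2)), "empty")
  set.seed(44)
  xy <- cbind(rnorm(101), rnorm(101))
  d <- sort(sqrt(rowSums(xy^2)))
  s <- distanceSummary(xy)
  expect_equal(unname(s["median"]), d[51])
  expect_equal(unname(s["q1"]), unname(stats::quantile(d, 0.25, type = 7)))
})

test_that("circular tests behave at concentration, symmetry and uniformity", {
  # all angles equal: maximal concentration
  eq <- rayleighTest(rep(1.3, 30))
  expect_equal(eq$statistic, 1, tolerance = 1e-12)
  expect_lt(eq$p_value, 0.001)
  # perfectly regular angles: resultant cancels
  reg <- rayleighTest(2 * pi * (0:35) / 36)
  expect_lt(reg$statistic, 1e-12)
  # Rbar equals the brute-force resultant computation
  set.seed(50)
  a <- runif(200, 0, 2 * pi)
  expect_equal(rayleighTest(a)$statistic,
               sqrt(sum(cos(a))^2 + sum(sin(a))^2) / 200,
               tolerance = 1e-12)
  # the battery returns all four tests and rejects a concentrated sample
  ct <- circularTests(rnorm(100, 2, 0.2) %% (2 * pi))
  expect_setequal(ct$test, c("rayleigh", "kuiper", "watson", "rao_spacing"))
  expect_true(all(ct$reject))
  expect_error(circularTests(1:4), "at least 5")
})
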
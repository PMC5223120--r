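# Spatial statistics of rejected-seed patterns: nearest-neighbour
# G-function, Monte-Carlo CSR envelopes, the DCLF goodness-of-fit test,
# characteristic clustering distances, radial density profiles and
# distance summaries.

#' Shrink a disc region by a border buffer
#'
#' The area of interest is the portion of the arena at least `buffer` cm
#' away from its border: a disc of radius `R - buffer`.
#'
#' @param region a disc region from [discRegion()].
#' @param buffer border buffer in cm (default 5).
#' @return the shrunken disc region.
#' @examples
#' areaOfInterest(discRegion(c(0, 0), 200), 5)$radius  # 195
#' @export
areaOfInterest <- function(region, buffer = 5) {
  if (region$type != "disc")
    stop("area of interest is defined for disc regions")
  if (buffer >= region$radius)
    stop("buffer must be smaller than the disc radius")
  if (buffer == 0) return(region)
  discRegion(region$centre, region$radius - buffer)
}

#' Restrict a pattern to a (sub)region
#'
#' Keeps only the points falling inside `region` and attaches that region
#' as the pattern's observation window.
#'
#' @param pattern a [PointPattern-class].
#' @param region a region list.
#' @return a [PointPattern-class].
#' @export
clipPattern <- function(pattern, region) {
  xy <- coords(pattern)
  keep <- regionContains(region, xy)
  pointPattern(xy[keep, , drop = FALSE], region)
}

#' Nearest-neighbour distances
#'
#' For each point, the Euclidean distance to its nearest other point
#' (grid-bucketed search, expected linear time). Duplicated locations yield
#' distance 0.
#'
#' @param pattern a [PointPattern-class] or an n x 2 coordinate matrix.
#' @return numeric vector of length n.
#' @export
nnDistances <- function(pattern) {
  xy <- if (is(pattern, "PointPattern")) coords(pattern) else as.matrix(pattern)
  n <- nrow(xy)
  if (n < 2L) stop("need >=2 points")
  nn_dist_cpp(xy[, 1], xy[, 2])
}

#' Nearest-neighbour G-function
#'
#' Empirical cumulative fraction of nearest-neighbour distances,
#' `G(d) = #\{NNdist <= d\} / n`, evaluated on a distance grid. No edge
#' correction is applied: the identical estimator is used for observed and
#' simulated patterns (the observation window is border-buffered upstream
#' instead, see [areaOfInterest()]).
#'
#' @param pattern a [PointPattern-class] (n >= 2) or a precomputed vector of
#'   nearest-neighbour distances.
#' @param dGrid increasing distance grid; default 512 equally spaced values
#'   from 0 to the region diameter.
#' @return data.frame with columns `d` and `G`.
#' @export
gFunction <- function(pattern, dGrid = NULL) {
  if (is(pattern, "PointPattern")) {
    nn <- nnDistances(pattern)
    if (is.null(dGrid))
      dGrid <- seq(0, regionDiameter(region(pattern)), length.out = 512L)
  } else {
    nn <- as.numeric(pattern)
    if (is.null(dGrid)) dGrid <- seq(0, max(nn), length.out = 512L)
  }
  data.frame(d = dGrid, G = .gOnGrid(nn, dGrid))
}

.gOnGrid <- function(nn, dGrid) {
  findInterval(dGrid, sort(nn)) / length(nn)
}

#' Simulate complete spatial randomness (CSR)
#'
#' Exactly `n` points, independent and uniform on the region (a binomial
#' process with fixed n, honouring "the same number of seeds" as the
#' observed pattern). Disc regions are sampled in closed form; polygons by
#' rejection from their bounding box.
#'
#' @param n number of points.
#' @param region a region list.
#' @param seed RNG seed (NULL = use the current RNG stream).
#' @return a [PointPattern-class].
#' @export
simulateCSR <- function(n, region, seed = NULL) {
  withSeed(seed, {
    if (n == 0L)
      return(pointPattern(matrix(numeric(), 0L, 2L), region))
    if (region$type == "disc") {
      r <- region$radius * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      xy <- cbind(region$centre[1] + r * cos(a),
                  region$centre[2] + r * sin(a))
    } else {
      v <- region$vertices
      lo <- apply(v, 2L, min); hi <- apply(v, 2L, max)
      xy <- matrix(numeric(), 0L, 2L)
      while (nrow(xy) < n) {
        m <- 2L * (n - nrow(xy)) + 10L
        cand <- cbind(stats::runif(m, lo[1], hi[1]),
                      stats::runif(m, lo[2], hi[2]))
        xy <- rbind(xy, cand[.pointInPolygon(cand, v), , drop = FALSE])
      }
      xy <- xy[seq_len(n), , drop = FALSE]
    }
    pointPattern(xy, region)
  })
}

#' Simulate a Thomas cluster process (fixed counts)
#'
#' `nParents` parent points are placed uniformly in the region; each parent
#' receives `nOffspring` offspring displaced by isotropic Gaussian noise
#' with standard deviation `sigma`, resampled until they fall inside the
#' region. Used as a known-clustered benchmark pattern.
#'
#' @param nParents,nOffspring counts.
#' @param sigma offspring dispersion (cm).
#' @param region a region list.
#' @param seed RNG seed.
#' @return a [PointPattern-class] with `nParents * nOffspring` points.
#' @export
simulateThomas <- function(nParents, nOffspring, sigma, region, seed = NULL) {
  withSeed(seed, {
    par <- coords(simulateCSR(nParents, region))
    pts <- matrix(numeric(), 0L, 2L)
    for (i in seq_len(nParents)) {
      need <- nOffspring
      while (need > 0L) {
        cand <- cbind(stats::rnorm(need, par[i, 1], sigma),
                      stats::rnorm(need, par[i, 2], sigma))
        ok <- regionContains(region, cand)
        pts <- rbind(pts, cand[ok, , drop = FALSE])
        need <- need - sum(ok)
      }
    }
    pointPattern(pts, region)
  })
}

#' Monte-Carlo CSR envelope of the G-function
#'
#' Simulates `nSim` CSR patterns with the same number of points in the same
#' region as the observed pattern, computes every G-curve on a shared grid
#' and returns the pointwise min/max envelope, the simulation mean, and the
#' per-simulation nearest-neighbour distances (kept for the characteristic
#' distance summaries).
#'
#' @param pattern observed [PointPattern-class] (n >= 2).
#' @param nSim number of CSR simulations (default 1000).
#' @param seed RNG seed (default 0).
#' @param dGrid distance grid; default 512 points from 0 to the region
#'   diameter.
#' @return an [EnvelopeResult-class].
#' @export
csrEnvelope <- function(pattern, nSim = 1000L, seed = 0, dGrid = NULL) {
  n <- nPoints(pattern)
  if (n < 2L) stop("need >=2 points")
  reg <- region(pattern)
  if (is.null(dGrid)) dGrid <- seq(0, regionDiameter(reg), length.out = 512L)
  obsNN <- nnDistances(pattern)
  obs <- .gOnGrid(obsNN, dGrid)
  nSim <- as.integer(nSim)
  simNN <- vector("list", nSim)
  curves <- matrix(0, nSim, length(dGrid))
  withSeed(seed, {
    for (i in seq_len(nSim)) {
      p <- simulateCSR(n, reg, seed = NULL)
      simNN[[i]] <- nnDistances(p)
      curves[i, ] <- .gOnGrid(simNN[[i]], dGrid)
    }
  })
  lo <- apply(curves, 2L, min)
  hi <- apply(curves, 2L, max)
  new("EnvelopeResult", dGrid = dGrid, obs = obs,
      simMean = colMeans(curves), lo = lo, hi = hi, simCurves = curves,
      obsNN = obsNN, simNN = simNN, nSim = nSim)
}

#' Diggle-Cressie-Loosmore-Ford (DCLF) goodness-of-fit test
#'
#' The test statistic is the integrated squared deviation of the G-curve
#' from the simulation mean over `[0, dMax]` (trapezoidal rule). With the
#' one-sided `"upper"` alternative only deviations above the reference
#' contribute (clustering: excess short nearest-neighbour distances); with
#' `"lower"` only deviations below; `"two.sided"` uses all deviations.
#' Each simulated pattern's statistic is computed against the mean of the
#' other simulations, preserving exchangeability, so the Monte-Carlo rank
#' test is exact: `p = rank / (nSim + 1)` with
#' `rank = 1 + #\{simulated u > u_obs\}`.
#'
#' @param env an [EnvelopeResult-class].
#' @param alternative "upper" (default; clustered alternative), "lower" or
#'   "two.sided".
#' @param dMax upper integration limit; default the 95th percentile of the
#'   pooled simulated nearest-neighbour distances. Must lie within the
#'   envelope's distance grid.
#' @param alpha significance level for the verdict (default 0.05).
#' @return a [DCLFResult-class].
#' @export
dclfTest <- function(env, alternative = c("upper", "lower", "two.sided"),
                     dMax = NULL, alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (is.null(dMax))
    dMax <- stats::quantile(unlist(env@simNN), 0.95, names = FALSE, type = 7)
  g <- env@dGrid
  if (dMax < g[1] || dMax > g[length(g)]) stop("dMax outside the distance grid")
  keep <- g <= dMax
  gk <- g[keep]
  devFun <- switch(alternative,
    upper = function(x) pmax(x, 0),
    lower = function(x) pmin(x, 0),
    two.sided = identity)
  u <- function(curve, refMean) {
    .trapz(gk, devFun(curve - refMean)^2)
  }
  nSim <- env@nSim
  simC <- env@simCurves[, keep, drop = FALSE]
  obsC <- env@obs[keep]
  meanC <- colMeans(simC)
  uObs <- u(obsC, meanC)
  if (nSim >= 2L) {
    tot <- colSums(simC)
    uSim <- vapply(seq_len(nSim), function(i)
      u(simC[i, ], (tot - simC[i, ]) / (nSim - 1L)), numeric(1))
  } else {
    uSim <- 0
  }
  rank <- 1L + sum(uSim > uObs)
  p <- rank / (nSim + 1L)
  verdict <- if (p <= alpha) {
    switch(alternative,
      upper = "clustered",
      lower = "regular",
      two.sided = if (.trapz(gk, obsC - meanC) >= 0) "clustered" else "regular")
  } else "CSR"
  new("DCLFResult", uObs = uObs, uSim = as.numeric(uSim),
      rank = as.integer(rank), p = p, verdict = verdict,
      alternative = alternative, dMax = as.numeric(dMax))
}

#' Characteristic clustering and CSR distances
#'
#' When a pattern is declared clustered, the cumulative fraction of its
#' G-curve lying strictly above the upper envelope bound defines
#' `f_star = max\{G_obs(d) : G_obs(d) > hi(d)\}`. The observed
#' nearest-neighbour distances up to their `f_star` quantile are summarized
#' as the characteristic clustering distance (median [Q1; Q3]); the same
#' per-simulation fraction of simulated nearest-neighbour distances, pooled
#' over all simulations, gives the characteristic CSR distance.
#'
#' Quartiles use the type-7 (linear interpolation) convention.
#'
#' @param env an [EnvelopeResult-class].
#' @param dclf the matching [DCLFResult-class]; when its verdict is not
#'   "clustered" the summaries are empty with `f_star = 0`.
#' @return list with `f_star`, `nndist_cluster` (named vector: median, q1,
#'   q3, n) and `nndist_csr` (same form, pooled over simulations).
#' @export
characteristicDistances <- function(env, dclf = NULL) {
  if (!is.null(dclf) && dclf@verdict != "clustered") {
    empty <- c(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0)
    return(list(f_star = 0, nndist_cluster = empty, nndist_csr = empty))
  }
  above <- env@obs > env@hi
  if (!any(above)) {
    empty <- c(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0)
    return(list(f_star = 0, nndist_cluster = empty, nndist_csr = empty))
  }
  fStar <- min(max(env@obs[above]), 1)
  summ <- function(x) {
    if (length(x) == 0L)
      return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0))
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    c(median = q[1], q1 = q[2], q3 = q[3], n = length(x))
  }
  qObs <- stats::quantile(env@obsNN, fStar, names = FALSE, type = 7)
  clu <- env@obsNN[env@obsNN <= qObs]
  csr <- unlist(lapply(env@simNN, function(nn) {
    qi <- stats::quantile(nn, fStar, names = FALSE, type = 7)
    nn[nn <= qi]
  }))
  list(f_star = fStar, nndist_cluster = summ(clu), nndist_csr = summ(csr))
}

#' Radial density profile
#'
#' Points are grouped into concentric rings of width `ringWidth` centred on
#' the nest (ring k covers `[k w, (k+1) w)`, half-open); the density is the
#' count divided by the ring area, rings being clipped to the disc region.
#'
#' @param pattern a [PointPattern-class] with a disc region.
#' @param ringWidth ring width in cm (default 10).
#' @param centre ring centre; defaults to the region centre.
#' @return data.frame with `inner`, `outer`, `count`, `area_cm2`,
#'   `density`.
#' @export
radialDensity <- function(pattern, ringWidth = 10, centre = NULL) {
  stopifnot(ringWidth > 0)
  reg <- region(pattern)
  if (reg$type != "disc") stop("radial density is defined for disc regions")
  if (is.null(centre)) centre <- reg$centre
  xy <- coords(pattern)
  R <- reg$radius
  nRings <- ceiling(R / ringWidth)
  inner <- (seq_len(nRings) - 1L) * ringWidth
  outer <- pmin(inner + ringWidth, R)
  if (nrow(xy) > 0) {
    d <- sqrt((xy[, 1] - centre[1])^2 + (xy[, 2] - centre[2])^2)
    counts <- vapply(seq_len(nRings), function(k)
      sum(d >= inner[k] & d < inner[k] + ringWidth), integer(1))
  } else counts <- integer(nRings)
  area <- pi * (outer^2 - inner^2)
  data.frame(inner = inner, outer = outer, count = counts, area_cm2 = area,
             density = counts / area)
}

#' Distance-to-nest summary
#'
#' Median and quartiles (type 7) of the Euclidean distances from the nest
#' origin.
#'
#' @param pattern a [PointPattern-class] or n x 2 coordinate matrix (cm,
#'   nest at the origin).
#' @return named vector `c(median, q1, q3, n)`.
#' @export
distanceSummary <- function(pattern) {
  xy <- if (is(pattern, "PointPattern")) coords(pattern) else as.matrix(pattern)
  if (nrow(xy) == 0L) stop("empty pattern")
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  q <- stats::quantile(d, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3], n = length(d))
}

#' Full spatial analysis of a rejected-seed pattern
#'
#' Convenience wrapper: buffers the arena border, restricts the pattern to
#' the area of interest, computes the CSR envelope, runs the DCLF test and
#' derives the characteristic distances.
#'
#' @param pattern a [PointPattern-class] whose region is the full arena
#'   disc.
#' @param buffer border buffer in cm (default 5).
#' @param nSim number of CSR simulations (default 1000).
#' @param seed RNG seed (default 0).
#' @param alpha significance level (default 0.05).
#' @param alternative DCLF alternative (default "upper").
#' @return list with `pattern` (clipped), `envelope`, `dclf`,
#'   `characteristic`, `summary` (distance summary of the clipped pattern).
#' @export
analyzePattern <- function(pattern, buffer = 5, nSim = 1000L, seed = 0,
                           alpha = 0.05, alternative = "upper") {
  aoi <- areaOfInterest(region(pattern), buffer)
  clipped <- clipPattern(pattern, aoi)
  env <- csrEnvelope(clipped, nSim = nSim, seed = seed)
  dclf <- dclfTest(env, alternative = alternative, alpha = alpha)
  list(pattern = clipped, envelope = env, dclf = dclf,
       characteristic = characteristicDistances(env, dclf),
       summary = distanceSummary(clipped))
}

#' Write an envelope/DCLF report as JSON
#'
#' @param analysis result of [analyzePattern()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writePatternReport <- function(analysis, path) {
  env <- analysis$envelope
  dclf <- analysis$dclf
  rep <- list(
    n = nPoints(analysis$pattern),
    d_grid = env@dGrid, observed = env@obs, sim_mean = env@simMean,
    lo = env@lo, hi = env@hi, n_sim = env@nSim,
    u_obs = dclf@uObs, rank = dclf@rank, p = dclf@p,
    verdict = dclf@verdict, d_max = dclf@dMax,
    f_star = analysis$characteristic$f_star,
    nndist_cluster = as.list(analysis$characteristic$nndist_cluster),
    nndist_csr = as.list(analysis$characteristic$nndist_csr),
    distance_summary = as.list(analysis$summary))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
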
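# Agent-based isotropic centrifugal seed-dropping simulator: "blind"
# carriers drop at a target distance drawn from a radial law; "reactive"
# carriers drop early the first time a previously dropped seed lies within
# their perception range.

#' Dispersal simulation configuration
#'
#' Carriers leave the nest (arena centre) one at a time at a uniformly
#' random heading and walk outward in straight steps of `stepCm` towards a
#' target distance drawn from the drop-distance law. Blind carriers drop
#' exactly at the target distance; reactive carriers drop at the current
#' position the first time any previously dropped seed lies within
#' `perceptionRangeCm`, otherwise at the target distance.
#'
#' Drop-distance laws: `"uniform-area"` (default) draws `r = R sqrt(U)`,
#' which makes blind dropping exactly complete spatial randomness on the
#' arena disc (median distance `R / sqrt(2)`, about 138 cm for the default
#' 195 cm radius of analysis -- close to observed median seed distances);
#' `"exponential"` draws from an exponential with mean `dropMeanCm`,
#' redrawing values beyond the arena radius (truncation), which
#' concentrates drops near the nest.
#'
#' @param model "blind" or "reactive".
#' @param nSeeds number of seeds to drop.
#' @param arenaRadiusCm arena radius (cm).
#' @param perceptionRangeCm reactive perception range (cm); default 0.5
#'   (5 mm).
#' @param dropLaw "uniform-area" or "exponential".
#' @param dropMeanCm mean of the exponential law (cm).
#' @param stepCm path discretisation step; must not exceed the perception
#'   range for reactive carriers (so a perception disc cannot be stepped
#'   over), default 0.25.
#' @param seed RNG seed.
#' @return a `DispersalConfig` list.
#' @export
dispersalConfig <- function(model = c("blind", "reactive"), nSeeds = 200L,
                            arenaRadiusCm = 200, perceptionRangeCm = 0.5,
                            dropLaw = c("uniform-area", "exponential"),
                            dropMeanCm = 141, stepCm = 0.25, seed = 0) {
  model <- match.arg(model)
  dropLaw <- match.arg(dropLaw)
  stopifnot(nSeeds >= 0, arenaRadiusCm > 0, perceptionRangeCm >= 0,
            stepCm > 0)
  if (model == "reactive" && perceptionRangeCm > 0 &&
      stepCm > perceptionRangeCm)
    stop("stepCm must not exceed perceptionRangeCm for the reactive model")
  structure(list(model = model, nSeeds = as.integer(nSeeds),
                 arenaRadiusCm = arenaRadiusCm,
                 perceptionRangeCm = perceptionRangeCm, dropLaw = dropLaw,
                 dropMeanCm = dropMeanCm, stepCm = stepCm, seed = seed),
            class = "DispersalConfig")
}

.drawTarget <- function(cfg) {
  R <- cfg$arenaRadiusCm
  if (cfg$dropLaw == "uniform-area") {
    R * sqrt(stats::runif(1))
  } else {
    repeat {
      r <- stats::rexp(1, rate = 1 / cfg$dropMeanCm)
      if (r <= R) return(r)
    }
  }
}

#' Run one dispersal simulation
#'
#' Seeds are dropped sequentially per the configured model; see
#' [dispersalConfig()]. With `classify = TRUE` the resulting pattern
#' (restricted to the border-buffered area of interest) is classified
#' against CSR with [csrEnvelope()] and [dclfTest()].
#'
#' @param cfg a [dispersalConfig()].
#' @param classify run the CSR classification (default FALSE).
#' @param nSimEnvelope simulations for the classification envelope
#'   (default 99).
#' @param buffer border buffer for the area of interest (default 5 cm).
#' @param alpha significance level (default 0.05).
#' @return list with `pattern` (a [PointPattern-class] on the arena disc),
#'   `cause` (per-seed: "target_distance" or "encounter") and, when
#'   classified, `classification` ("clustered", "CSR" or "regular") and
#'   `dclf`.
#' @export
simulateDispersal <- function(cfg, classify = FALSE, nSimEnvelope = 99L,
                              buffer = 5, alpha = 0.05) {
  R <- cfg$arenaRadiusCm
  rng <- cfg$perceptionRangeCm
  step <- cfg$stepCm
  reactive <- cfg$model == "reactive" && rng > 0
  xs <- numeric(cfg$nSeeds); ys <- numeric(cfg$nSeeds)
  cause <- character(cfg$nSeeds)
  withSeed(cfg$seed, {
    for (k in seq_len(cfg$nSeeds)) {
      theta <- stats::runif(1, 0, 2 * pi)
      target <- .drawTarget(cfg)
      ux <- cos(theta); uy <- sin(theta)
      dropR <- target
      why <- "target_distance"
      if (reactive && k > 1L) {
        px <- xs[seq_len(k - 1L)]; py <- ys[seq_len(k - 1L)]
        tproj <- px * ux + py * uy
        lat2 <- px * px + py * py - tproj * tproj
        ok <- lat2 <= rng^2
        if (any(ok)) {
          delta <- sqrt(rng^2 - lat2[ok])
          lo <- tproj[ok] - delta
          hi <- tproj[ok] + delta
          # first discrete step position falling inside a perception
          # interval, capped by the target distance
          jlo <- pmax(ceiling(lo / step), 1)
          rCand <- jlo * step
          hit <- rCand <= hi & rCand <= target
          if (any(hit)) {
            dropR <- min(rCand[hit])
            why <- "encounter"
          }
        }
      }
      xs[k] <- dropR * ux; ys[k] <- dropR * uy
      cause[k] <- why
    }
  })
  pat <- pointPattern(cbind(xs, ys), discRegion(c(0, 0), R))
  out <- list(pattern = pat, cause = cause)
  if (classify) {
    aoi <- areaOfInterest(discRegion(c(0, 0), R), buffer)
    clipped <- clipPattern(pat, aoi)
    if (nPoints(clipped) < 2L) {
      out$classification <- "CSR"
    } else {
      env <- csrEnvelope(clipped, nSim = nSimEnvelope,
                         seed = .deriveSeed(cfg$seed, 1L))
      dclf <- dclfTest(env, alternative = "upper", alpha = alpha)
      out$classification <- dclf@verdict
      out$dclf <- dclf
    }
  }
  out
}

# derive a distinct 31-bit sub-seed from a base seed and an index
.deriveSeed <- function(seed, i) {
  (as.numeric(seed) * 1103L + i * 12347) %% 2147483647
}

#' Fraction of simulation runs classified as clustered
#'
#' Repeats [simulateDispersal()] `nRuns` times with distinct sub-seeds,
#' classifies each resulting pattern against CSR (envelope of
#' `nSimEnvelope` simulations, DCLF upper test at `alpha`) and returns the
#' fraction of runs declared clustered.
#'
#' @param cfg a [dispersalConfig()]; its `seed` is the base seed.
#' @param nRuns number of independent runs.
#' @param nSimEnvelope,buffer,alpha classification settings (see
#'   [simulateDispersal()]).
#' @return list with `fraction`, `verdicts` (character vector) and
#'   `causeEncounterRate` (mean fraction of seeds dropped on encounter).
#' @export
clusteringFraction <- function(cfg, nRuns = 50L, nSimEnvelope = 99L,
                               buffer = 5, alpha = 0.05) {
  stopifnot(nRuns >= 1L)
  verdicts <- character(nRuns)
  encRate <- numeric(nRuns)
  for (i in seq_len(nRuns)) {
    cfgI <- cfg
    cfgI$seed <- .deriveSeed(cfg$seed, 1000L + i)
    sim <- simulateDispersal(cfgI, classify = TRUE,
                             nSimEnvelope = nSimEnvelope, buffer = buffer,
                             alpha = alpha)
    verdicts[i] <- sim$classification
    encRate[i] <- mean(sim$cause == "encounter")
  }
  list(fraction = mean(verdicts == "clustered"), verdicts = verdicts,
       causeEncounterRate = mean(encRate))
}
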
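# Circular uniformity tests: Rayleigh, Kuiper, Watson and Rao's spacing.

#' Rayleigh test of circular uniformity
#'
#' Mean resultant length Rbar of the angles; the p-value uses the standard
#' series approximation
#' `p = exp(-n Rbar^2) (1 + (2 n Rbar^2 - n^2 Rbar^4) / (4 n))`.
#' Sensitive to unimodal departures from uniformity.
#'
#' @param angles numeric vector of angles in radians.
#' @return list with `statistic` (Rbar), `p_value`, `n`.
#' @export
rayleighTest <- function(angles) {
  n <- length(angles)
  C <- sum(cos(angles)); S <- sum(sin(angles))
  rbar <- sqrt(C^2 + S^2) / n
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
  list(statistic = rbar, p_value = max(min(p, 1), 0), n = n)
}

#' Kuiper test of circular uniformity
#'
#' Rotation-invariant analogue of Kolmogorov-Smirnov: `V = D+ + D-` on the
#' angles rescaled to [0, 1). The p-value uses Stephens' modified statistic
#' `V* = V (sqrt(n) + 0.155 + 0.24 / sqrt(n))` with the asymptotic series
#' `p = 2 sum_m (4 m^2 V*^2 - 1) exp(-2 m^2 V*^2)`.
#'
#' @inheritParams rayleighTest
#' @return list with `statistic` (V), `p_value`, `n`.
#' @export
kuiperTest <- function(angles) {
  n <- length(angles)
  u <- sort((angles %% (2 * pi)) / (2 * pi))
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  V <- dplus + dminus
  vs <- V * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  m <- 1:10
  p <- 2 * sum((4 * m^2 * vs^2 - 1) * exp(-2 * m^2 * vs^2))
  list(statistic = V, p_value = max(min(p, 1), 0), n = n)
}

#' Watson U^2 test of circular uniformity
#'
#' Rotation-invariant Cramer-von-Mises analogue. The p-value uses the
#' modified statistic `U*^2 = (U^2 - 0.1/n + 0.1/n^2)(1 + 0.8/n)` with the
#' asymptotic tail `p = 2 sum_m (-1)^(m-1) exp(-2 m^2 pi^2 U*^2)`.
#'
#' @inheritParams rayleighTest
#' @return list with `statistic` (U^2), `p_value`, `n`.
#' @export
watsonTest <- function(angles) {
  n <- length(angles)
  u <- sort((angles %% (2 * pi)) / (2 * pi))
  i <- seq_len(n)
  ubar <- mean(u)
  U2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n) - n * (ubar - 0.5)^2
  us <- (U2 - 0.1 / n + 0.1 / n^2) * (1 + 0.8 / n)
  m <- 1:10
  p <- 2 * sum((-1)^(m - 1) * exp(-2 * m^2 * pi^2 * us))
  list(statistic = U2, p_value = max(min(p, 1), 0), n = n)
}

# Rao spacing statistic (radians): U = 0.5 * sum |T_i - 2*pi/n|
.raoStatistic <- function(angles) {
  n <- length(angles)
  a <- sort(angles %% (2 * pi))
  sp <- c(diff(a), 2 * pi - a[n] + a[1])
  0.5 * sum(abs(sp - 2 * pi / n))
}

# cache of Monte-Carlo null samples of the Rao statistic, keyed by n
.raoNullCache <- new.env(parent = emptyenv())

.raoNull <- function(n, nSim = 2000L) {
  key <- as.character(n)
  if (!is.null(.raoNullCache[[key]])) return(.raoNullCache[[key]])
  # fixed internal seed: the null distribution is a property of n only
  sims <- withSeed(987654L + n, {
    vapply(seq_len(nSim), function(i)
      .raoStatistic(stats::runif(n, 0, 2 * pi)), numeric(1))
  })
  .raoNullCache[[key]] <- sims
  sims
}

#' Rao's spacing test of circular uniformity
#'
#' Statistic `U = 1/2 sum |T_i - 2 pi / n|` over the circular spacings
#' `T_i`. Large U (irregular spacings) indicates departure from uniformity.
#' The null distribution is obtained by Monte-Carlo simulation under
#' uniformity (2000 samples, fixed internal seed, cached per n), giving a
#' Monte-Carlo p-value `(1 + #\{U_sim >= U\}) / (nSim + 1)`.
#'
#' @inheritParams rayleighTest
#' @param nSimNull Monte-Carlo null sample size (default 2000).
#' @return list with `statistic` (U, radians), `p_value`, `n`.
#' @export
raoSpacingTest <- function(angles, nSimNull = 2000L) {
  n <- length(angles)
  U <- .raoStatistic(angles)
  sims <- .raoNull(n, nSimNull)
  p <- (1 + sum(sims >= U)) / (length(sims) + 1)
  list(statistic = U, p_value = p, n = n)
}

#' Battery of circular uniformity tests
#'
#' Runs the Rayleigh, Kuiper, Watson and Rao spacing tests on a set of
#' angles (for seed patterns: the polar angles of seed positions around the
#' nest).
#'
#' @param angles numeric vector of angles in radians (n >= 5).
#' @param alpha significance level for the verdicts (default 0.05).
#' @return data.frame with columns `test`, `statistic`, `p_value`,
#'   `reject`.
#' @examples
#' set.seed(1)
#' circularTests(runif(100, 0, 2 * pi))
#' @export
circularTests <- function(angles, alpha = 0.05) {
  if (length(angles) < 5L) stop("need at least 5 angles")
  res <- list(
    rayleigh = rayleighTest(angles),
    kuiper = kuiperTest(angles),
    watson = watsonTest(angles),
    rao_spacing = raoSpacingTest(angles))
  data.frame(
    test = names(res),
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    p_value = vapply(res, function(r) r$p_value, numeric(1)),
    reject = vapply(res, function(r) r$p_value <= alpha, logical(1)),
    row.names = NULL)
}

#' Polar angles of a point pattern around the nest
#'
#' @param pattern a [PointPattern-class] or n x 2 matrix (nest at origin).
#' @return angles in radians in [0, 2 pi).
#' @export
patternAngles <- function(pattern) {
  xy <- if (is(pattern, "PointPattern")) coords(pattern) else as.matrix(pattern)
  atan2(xy[, 2], xy[, 1]) %% (2 * pi)
}
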
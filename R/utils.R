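#' @importFrom stats dnorm pnorm qnorm runif rnorm rbinom optim uniroot
#'   t.test cor.test aov median sd var plogis qlogis setNames
#' @importFrom rlang abort warn hash
#' @importFrom utils packageVersion
NULL

#' Derive a named random substream seed from a master seed
#'
#' All randomness in the package flows from a single integer seed. Each stage
#' (population sampling, trial simulation, drug assignment, bootstrap) draws
#' from its own substream so that re-running a stage in isolation reproduces
#' its output. The substream seed is a deterministic 31-bit hash of the master
#' seed and the stream name.
#'
#' @param seed Master integer seed.
#' @param name Character stream name, e.g. `"trials"`.
#' @return An integer in `[0, 2^31 - 1]` usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "population")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- (seed %% 2147483647) + 1
  for (code in utf8ToInt(name)) {
    # 31-bit multiplicative hash; constants fixed, no global RNG state touched
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a truncated normal distribution by inverse-CDF sampling
#'
#' @param n Number of draws.
#' @param mean,sd Parent normal parameters.
#' @param lower,upper Truncation bounds (inclusive support).
#' @return Numeric vector of length `n`.
#' @keywords internal
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Moments of a truncated normal distribution
#'
#' Used for moment-matching the trait (AQ) distribution when calibrating the
#' trait-to-PSE regression to a target correlation.
#'
#' @inheritParams rnorm_trunc
#' @return List with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(list(mean = mean, sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  av <- if (is.finite(a)) a * da else 0
  bv <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (av - bv) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}
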
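#' Inverse-logit (expit) transform
#'
#' @param x numeric vector of log-odds.
#' @return numeric vector of probabilities.
#' @export
expit <- function(x) stats::plogis(x)

#' Logit transform
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return numeric vector of log-odds.
#' @export
logit <- function(p) stats::qlogis(p)

# Predicted risks are clipped away from 0/1 so that log-likelihoods and
# logits stay finite; the clip bound is far below any resolvable risk.
PROB_EPS <- 1e-10

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Derive a reproducible substream seed
#'
#' Counter-based seed derivation: mixes a master seed with any number of
#' integer counters (scenario index, replicate index, attempt number) into a
#' new seed in `[0, 2^31 - 2]`. Scenarios and replicates are independent work
#' units, so seeds must not collide or depend on execution order; a
#' multiplicative mixing scheme on exact double arithmetic (< 2^53) gives
#' every `(master, counters...)` tuple its own stream.
#'
#' @param master integer master seed.
#' @param ... integer counters identifying the substream.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  counters <- c(master, ...)
  s <- 0
  for (v in counters) {
    # 69069 is the classic Marsaglia multiplier; modulus 2^31 - 1 keeps the
    # product below 2^53 so doubles are exact.
    s <- (s * 69069 + (as.numeric(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s)
}

# Upper-quadrant probability P(Z1 > t1, Z2 > t2) for standard bivariate
# normal with correlation r, by one-dimensional quadrature. Used to solve
# latent correlations for binary-involved proxy constructions.
bvn_upper <- function(t1, t2, r) {
  if (abs(r) < 1e-12) return((1 - stats::pnorm(t1)) * (1 - stats::pnorm(t2)))
  f <- function(z) {
    stats::dnorm(z) * (1 - stats::pnorm((t2 - r * z) / sqrt(1 - r^2)))
  }
  stats::integrate(f, lower = t1, upper = Inf, rel.tol = 1e-10)$value
}

# Observed-scale Pearson correlation implied by latent-Gaussian correlation r
# for a pair of thresholded / identity margins.
#  kind "cc": both continuous            -> r itself
#  kind "cb": one continuous, one binary -> point-biserial r * dnorm(t)/sd(B)
#  kind "bb": both binary                -> (P11 - p1 p2) / (sd1 sd2)
implied_obs_corr <- function(r, kind, p1 = NULL, p2 = NULL) {
  switch(kind,
    cc = r,
    cb = {
      t2 <- stats::qnorm(1 - p2)
      r * stats::dnorm(t2) / sqrt(p2 * (1 - p2))
    },
    bb = {
      t1 <- stats::qnorm(1 - p1)
      t2 <- stats::qnorm(1 - p2)
      (bvn_upper(t1, t2, r) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    },
    stop("unknown margin kind: ", kind)
  )
}

# Solve the latent-Gaussian correlation whose observed-scale Pearson
# correlation equals rho (bisection via uniroot; monotone in r).
solve_latent_corr <- function(rho, kind, p1 = NULL, p2 = NULL) {
  if (rho == 0) return(0)
  f <- function(r) implied_obs_corr(r, kind, p1, p2) - rho
  upper <- 1 - 1e-9
  if (f(upper) < 0) {
    stop("requested correlation ", rho,
         " is not attainable for these margins")
  }
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-10)$root
}
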
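# Independent brute-force / direct-optimisation oracles used to validate
# the package's O(n log n) and IRLS implementations on small fixtures.

# C statistic by explicit enumeration of all event/non-event pairs.
brute_c_statistic <- function(p, y) {
  pe <- p[y == 1]
  pn <- p[y == 0]
  if (!length(pe) || !length(pn)) return(NA_real_)
  tot <- 0
  for (a in pe) tot <- tot + sum(a > pn) + 0.5 * sum(a == pn)
  tot / (length(pe) * length(pn))
}

# Gini mean difference by explicit enumeration of unordered pairs.
brute_g_index <- function(lp) {
  n <- length(lp)
  tot <- 0
  for (i in seq_len(n - 1)) {
    tot <- tot + sum(abs(lp[i] - lp[(i + 1):n]))
  }
  tot / (n * (n - 1) / 2)
}

binom_loglik <- function(p, y) sum(y * log(p) + (1 - y) * log(1 - p))

# Direct likelihood maximisation of a logistic model (quasi-Newton on the
# negative log-likelihood), independent of IRLS.
oracle_logistic <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  nll <- function(b) {
    p <- plogis(drop(X %*% b))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Two-parameter likelihood grid search for the recalibration fit,
# iteratively refined around the running optimum.
oracle_recalibration <- function(p, y) {
  x <- qlogis(pmin(pmax(p, 1e-10), 1 - 1e-10))
  ll <- function(a, b) {
    q <- plogis(a + b * x)
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    sum(y * log(q) + (1 - y) * log(1 - q))
  }
  a0 <- 0; b0 <- 1; half_a <- 5; half_b <- 5
  for (round in 1:6) {
    as <- seq(a0 - half_a, a0 + half_a, length.out = 41)
    bs <- seq(b0 - half_b, b0 + half_b, length.out = 41)
    vals <- outer(as, bs, Vectorize(ll))
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    a0 <- as[best[1]]; b0 <- bs[best[2]]
    half_a <- half_a / 8; half_b <- half_b / 8
  }
  c(a = a0, b = b0)
}

# Small logistic fixture with a known generating model.
make_fixture <- function(n, beta0 = 0, beta1 = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(beta0 + beta1 * x))
  list(X = data.frame(x1 = x), y = y)
}

# Tiny univariate scenario used across module tests (small n so suites
# stay fast; full study sizes are exercised in the acceptance tests).
tiny_uni_spec <- function(n_total = 1000L, beta1 = log(2), seed = 11L,
                          kind = "continuous", beta0 = qlogis(0.3)) {
  scenario_spec("tiny_uni", "univariate", kind, beta0 = beta0,
                betas = beta1, n_total = n_total, n_reps = 5L, seed = seed)
}

tiny_mul_spec <- function(n_total = 1000L, betas = log(c(2, 2)), seed = 12L,
                          kinds = c("continuous", "continuous"),
                          causal_corr = 0) {
  scenario_spec("tiny_mul", "multivariate", kinds, beta0 = qlogis(0.3),
                betas = betas, causal_corr = causal_corr,
                n_total = n_total, n_reps = 5L, seed = seed)
}
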
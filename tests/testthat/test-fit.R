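test_that("maximum-likelihood fit recovers generating coefficients", {
  fx <- make_fixture(12000, beta0 = 0, beta1 = log(2), seed = 21)
  fit <- fit_logistic(fx$X, fx$y)
  gf <- glm(fx$y ~ fx$X$x1, family = binomial())
  se <- sqrt(diag(vcov(gf)))[2]
  expect_lt(abs(fit$coefficients[["x1"]] - log(2)), 3 * se)
  expect_true(fit$converged)
  expect_gte(fit$train_lr_chi2, 0)
})

test_that("fit agrees with direct likelihood maximisation on small fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- data.frame(x1 = rnorm(20), x2 = rbinom(20, 1, 0.5))
    y <- rbinom(20, 1, plogis(0.3 * X$x1 - 0.2 * X$x2))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(X, y)
    if (!fit$converged) next  # separation capped; oracle diverges too
    oracle <- oracle_logistic(X, y)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  }
})

test_that("intercept-only fit has closed form and zero LR chi-square", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(data.frame(row.names = seq_along(y)), y)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), qlogis(0.3))
  expect_equal(fit$train_lr_chi2, 0)
  expect_identical(fit$df_model, 0L)
})

test_that("complete separation is capped and flagged", {
  X <- data.frame(x1 = c(-(10:1), 1:10))
  y <- rep(c(0, 1), each = 10)
  fit <- suppressWarnings(fit_logistic(X, y))
  expect_false(fit$converged)
  expect_true(all(abs(fit$coefficients) <= 15))
  # predictions still usable
  ps <- predict_risk(fit, X, y = y)
  expect_true(all(ps$p_hat > 0 & ps$p_hat < 1))
})

test_that("predicted risks match brute-force arithmetic and are monotone", {
  fit <- structure(list(
    variable_names = c("a", "b"),
    coefficients = c("(Intercept)" = -0.5, a = 1.2, b = -0.7),
    df_model = 2L, train_loglik = NA_real_, train_null_loglik = NA_real_,
    train_lr_chi2 = NA_real_, converged = TRUE), class = "fitted_logistic")
  X <- data.frame(a = c(-1, 0, 0.5, 1, 2), b = c(0, 1, -1, 0.3, -0.2))
  ps <- predict_risk(fit, X)
  expect_equal(ps$p_hat,
               plogis(-0.5 + 1.2 * X$a - 0.7 * X$b), tolerance = 1e-12)
  X2 <- X; X2$a <- X2$a + 1
  expect_true(all(predict_risk(fit, X2)$p_hat > ps$p_hat))
  expect_error(predict_risk(fit, X[, "a", drop = FALSE]), "b")
})

test_that("zero-coefficient model predicts one half everywhere", {
  fit <- structure(list(
    variable_names = "a",
    coefficients = c("(Intercept)" = 0, a = 0),
    df_model = 1L, train_loglik = NA_real_, train_null_loglik = NA_real_,
    train_lr_chi2 = NA_real_, converged = TRUE), class = "fitted_logistic")
  ps <- predict_risk(fit, data.frame(a = rnorm(7)))
  expect_equal(ps$p_hat, rep(0.5, 7))
})

test_that("heuristic shrinkage factor follows its arithmetic", {
  fake <- function(chi2, df) {
    structure(list(variable_names = paste0("v", seq_len(df)),
                   coefficients = NULL, df_model = df,
                   train_lr_chi2 = chi2, converged = TRUE),
              class = "fitted_logistic")
  }
  expect_equal(heuristic_shrinkage(fake(50, 2)), 0.96)
  expect_equal(heuristic_shrinkage(fake(0.5, 1)), -1.0)
  expect_true(is.na(heuristic_shrinkage(NULL)))
  expect_true(is.na(heuristic_shrinkage(fake(0, 1))))
  # gamma <= 1 always
  for (chi2 in c(0.1, 1, 10, 1000)) {
    expect_lte(heuristic_shrinkage(fake(chi2, 3)), 1)
  }
})

test_that("shrinkage scales slopes by gamma and recalibrates the intercept", {
  fx <- make_fixture(3000, beta1 = log(3), seed = 31)
  fit <- fit_logistic(fx$X, fx$y)
  gamma <- heuristic_shrinkage(fit)
  shr <- shrink_model(fit, fx$X, fx$y)
  expect_equal(shr$coefficients[["x1"]], gamma * fit$coefficients[["x1"]],
               tolerance = 1e-12)
  # strong effect at n = 3000: gamma near 1, coefficients nearly unchanged
  expect_gt(gamma, 0.9)
  # mean shrunken prediction matches the training prevalence (intercept refit)
  ps <- predict_risk(shr, fx$X)
  expect_lt(abs(mean(ps$p_hat) - mean(fx$y)), 0.01)
})

test_that("shrinkage moves the test calibration slope toward one when overfit", {
  set.seed(32)
  wins <- 0L
  for (i in 1:10) {
    n <- 120
    X <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("x", 1:6))))
    y <- rbinom(n, 1, plogis(0.5 * X$x1))
    Xt <- as.data.frame(matrix(rnorm(2000 * 6), 2000,
                               dimnames = list(NULL, paste0("x", 1:6))))
    yt <- rbinom(2000, 1, plogis(0.5 * Xt$x1))
    fit <- suppressWarnings(fit_logistic(X, y))
    if (is.na(heuristic_shrinkage(fit))) next
    shr <- shrink_model(fit, X, y)
    b_raw <- logistic_recalibration(predict_risk(fit, Xt)$p_hat, yt)$b_hat
    b_shr <- logistic_recalibration(predict_risk(shr, Xt)$p_hat, yt)$b_hat
    if (abs(b_shr - 1) < abs(b_raw - 1)) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("stepwise AIC keeps strong signals, honours exclusions, improves AIC", {
  set.seed(33)
  n <- 2000
  X <- data.frame(x1 = rnorm(n))
  X$noise1 <- rnorm(n)
  X$noise2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(log(4) * X$x1))
  sel <- stepwise_aic(X, y, pool = names(X))
  expect_true("x1" %in% sel$variable_names)

  excl <- stepwise_aic(X, y, pool = names(X), forced_out = "x1")
  expect_false("x1" %in% excl$variable_names)

  # single-variable pool returns that model unchanged
  single <- stepwise_aic(X, y, pool = "x1")
  expect_identical(single$variable_names, "x1")

  # AIC of the selection never exceeds AIC of the start model
  aic <- function(f) -2 * f$train_loglik + 2 * (f$df_model + 1)
  start <- fit_logistic(X, y)
  expect_lte(aic(sel), aic(start) + 1e-8)
})

test_that("stepwise selection drops pure noise in most replicates", {
  set.seed(34)
  kept_noise <- 0L
  for (i in 1:20) {
    n <- 1500
    X <- data.frame(x1 = rnorm(n), noise = rnorm(n))
    y <- rbinom(n, 1, plogis(log(4) * X$x1))
    sel <- stepwise_aic(X, y, pool = names(X))
    expect_true("x1" %in% sel$variable_names)
    if ("noise" %in% sel$variable_names) kept_noise <- kept_noise + 1L
  }
  # AIC keeps a noise term with probability ~ P(chi2_1 > 2) ~ 0.16
  expect_lte(kept_noise, 10L)
})
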
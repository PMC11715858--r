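test_that("C statistic equals brute-force pair counting, with ties", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(c_statistic(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(c_statistic(runif(5), rep(1, 5))))
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    p <- round(runif(n), 1)  # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(p, y), brute_c_statistic(p, y),
                 tolerance = 1e-12)
  }
})

test_that("C statistic agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  p <- runif(300)
  y <- rbinom(300, 1, p)
  expect_equal(c_statistic(p, y),
               as.numeric(suppressMessages(pROC::auc(y, p))),
               tolerance = 1e-10)
})

test_that("Dxy is twice the distance of the AUC from one half", {
  set.seed(43)
  for (i in 1:10) {
    p <- runif(60)
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(somers_dxy(p, y), 2 * (c_statistic(p, y) - 0.5),
                 tolerance = 1e-12)
  }
  expect_equal(somers_dxy(rep(0.2, 10), rep(c(0, 1), 5)), 0)
})

test_that("g-index equals brute-force pair means", {
  expect_equal(g_index(c(0, 1)), 1)
  expect_equal(g_index(c(1, 2, 4)), 2)
  expect_equal(g_index(rep(0.7, 9)), 0)
  set.seed(44)
  for (i in 1:15) {
    lp <- rnorm(sample(2:200, 1), sd = 2)
    expect_equal(g_index(lp), brute_g_index(lp), tolerance = 1e-10)
  }
})

test_that("logistic recalibration matches a likelihood grid search", {
  set.seed(45)
  p <- plogis(rnorm(8, sd = 1.2))
  y <- c(0, 1, 1, 0, 1, 0, 0, 1)
  cal <- logistic_recalibration(p, y)
  oracle <- oracle_recalibration(p, y)
  expect_equal(cal$a_hat, unname(oracle["a"]), tolerance = 1e-4)
  expect_equal(cal$b_hat, unname(oracle["b"]), tolerance = 1e-4)
  expect_gte(cal$loglik_free, cal$loglik_identity - 1e-8)
  expect_gte(cal$loglik_free, cal$loglik_null - 1e-8)
})

test_that("recalibration of a well-specified model approaches identity", {
  set.seed(46)
  n <- 20000
  x <- rnorm(n)
  p <- plogis(-0.5 + x)
  y <- rbinom(n, 1, p)
  cal <- logistic_recalibration(p, y)
  # (a, b) within 3 SE of (0, 1): SEs from the refit itself
  fit <- glm(y ~ qlogis(p), family = binomial())
  ses <- sqrt(diag(vcov(fit)))
  expect_lt(abs(cal$a_hat), 3 * ses[1])
  expect_lt(abs(cal$b_hat - 1), 3 * ses[2])
})

test_that("degenerate recalibration reduces to the observed rate", {
  y <- rep(c(1, 0), c(34, 66))
  cal <- logistic_recalibration(rep(0.5, 100), y)
  expect_true(cal$degenerate)
  expect_equal(cal$a_hat, qlogis(0.34))
})

test_that("U, D, Q satisfy their defining identities", {
  set.seed(47)
  for (i in 1:10) {
    n <- 500
    p <- runif(n, 0.05, 0.95)
    y <- rbinom(n, 1, p)
    udq <- udq_indices(logistic_recalibration(p, y), n)
    expect_equal(udq[["Q"]], udq[["D"]] - udq[["U"]], tolerance = 1e-12)
  }
  # flip-coin: the free fit equals the null fit, so D = -1/n exactly
  y <- rep(c(1, 0), c(30, 70))
  udq <- udq_indices(logistic_recalibration(rep(0.5, 100), y), 100)
  expect_equal(udq[["D"]], -1 / 100, tolerance = 1e-12)
})

test_that("calibration-in-the-large OR is predicted over observed odds", {
  y <- rep(c(1, 0), c(20, 80))
  expect_equal(calibration_large_or(rep(0.2, 100), y), 1.0)
  expect_equal(calibration_large_or(rep(1 / 3, 100), y), 2.0)
  expect_true(is.na(calibration_large_or(runif(5), rep(1, 5))))
  # direction fixed by the flip-coin reconstruction: constant 0.5
  # predictions against rate 0.168 give 1/odds(0.168)
  y2 <- rep(c(1, 0), c(168, 832))
  expect_equal(calibration_large_or(rep(0.5, 1000), y2),
               1 / (0.168 / 0.832), tolerance = 1e-12)
})

test_that("logistic-calibration errors follow the recalibration curve", {
  p <- c(0.1, 0.25, 0.4, 0.6, 0.8)
  id <- structure(list(a_hat = 0, b_hat = 1, degenerate = FALSE),
                  class = "calib_fit")
  e <- calibration_errors_logistic(p, rbinom(5, 1, p), calib = id)
  expect_equal(unname(e), rep(0, 4), tolerance = 1e-12)

  shift <- structure(list(a_hat = 0.5, b_hat = 1, degenerate = FALSE),
                     class = "calib_fit")
  e2 <- calibration_errors_logistic(p, rbinom(5, 1, p), calib = shift)
  curve <- function(q) plogis(0.5 + qlogis(q))
  grid <- seq(0.001, 0.999, by = 0.001)
  expect_equal(e2[["Emax_ab"]], max(abs(p - curve(p))), tolerance = 1e-12)
  expect_equal(e2[["E_abMean"]], mean(abs(p - curve(p))), tolerance = 1e-12)
  expect_equal(e2[["Emax_01"]], max(abs(grid - curve(grid))),
               tolerance = 1e-12)
  expect_equal(e2[["E_01Mean"]], mean(abs(grid - curve(grid))),
               tolerance = 1e-12)
})

test_that("constant predictions give the degenerate error pattern", {
  y <- rep(c(1, 0), c(34, 66))
  e <- calibration_errors_logistic(rep(0.5, 100), y)
  expect_equal(e[["Emax_ab"]], 0.16, tolerance = 1e-10)
  expect_equal(e[["Emax_01"]], 0.16, tolerance = 1e-10)
  expect_true(is.na(e[["E_abMean"]]))
  expect_true(is.na(e[["E_01Mean"]]))
})

test_that("LOWESS calibration errors behave at the extremes", {
  y <- rep(c(0, 1), each = 100)
  p <- pmin(pmax(y, 1e-10), 1 - 1e-10)
  low <- lowess_calibration(p, y)
  expect_lt(low[["Eavg_LOWESS"]], 1e-6)
  expect_lt(low[["ECI_LOWESS"]], 1e-6)

  y2 <- rep(c(1, 0), c(30, 70))
  low2 <- lowess_calibration(rep(0.5, 100), y2)
  expect_equal(low2[["Eavg_LOWESS"]], abs(0.5 - 0.3), tolerance = 1e-12)
  expect_equal(low2[["ECI_LOWESS"]], 100 * (0.5 - 0.3)^2, tolerance = 1e-12)
})

test_that("Brier score is the mean squared prediction error", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.2, 0.8, 0.5), c(0, 1, 1)),
               (0.04 + 0.04 + 0.25) / 3)
})

test_that("pseudo R-squares vanish at the null model and obey orderings", {
  y <- rep(c(1, 0), c(40, 60))
  r2 <- pseudo_r2_panel(rep(0.4, 100), y, k = 0)
  likelihood_based <- c("R2_Nagelkerke", "R2_McFadden", "R2_McFaddenAdj",
                        "R2_CoxSnell", "R2_AldrichNelson",
                        "R2_VeallZimmermann", "R2_Efron", "R2_Tjur")
  expect_equal(unname(r2[likelihood_based]), rep(0, 8), tolerance = 1e-9)

  set.seed(48)
  fx <- make_fixture(500, beta1 = 1, seed = 48)
  fit <- fit_logistic(fx$X, fx$y)
  ps <- predict_risk(fit, fx$X, y = fx$y)
  r2f <- pseudo_r2_panel(ps$p_hat, fx$y, k = 1)
  expect_lte(r2f[["R2_CoxSnell"]], r2f[["R2_Nagelkerke"]])
  expect_lte(r2f[["R2_McFaddenAdj"]], r2f[["R2_McFadden"]])
  n <- 500
  L0 <- sum(fx$y * log(mean(fx$y)) + (1 - fx$y) * log(1 - mean(fx$y)))
  expect_lt(r2f[["R2_CoxSnell"]], 1 - exp(2 * L0 / n))
})

test_that("Tjur R-squared and IDI against null agree exactly", {
  p <- c(0.8, 0.6, 0.3, 0.3)
  y <- c(1, 1, 0, 0)
  expect_equal(pseudo_r2_panel(p, y)[["R2_Tjur"]], 0.40, tolerance = 1e-12)
  expect_equal(idi(p, y = y), 0.40, tolerance = 1e-12)
  expect_equal(idi(p, p, y), 0)
  set.seed(49)
  for (i in 1:10) {
    p <- runif(80)
    y <- rbinom(80, 1, p)
    if (length(unique(y)) < 2) next
    expect_equal(idi(p, y = y), pseudo_r2_panel(p, y)[["R2_Tjur"]],
                 tolerance = 1e-10)
  }
})

test_that("the full panel has 25 slots and the flip-coin pattern", {
  y <- rbinom(200, 1, 0.4)
  fc <- flip_coin_model(200, y)
  pan <- measure_panel(fc)
  expect_identical(names(pan), MEASURE_NAMES)
  expect_length(pan, 25L)
  expect_equal(pan[["AUC"]], 0.5)
  expect_equal(pan[["brierScore"]], 0.25)
  expect_equal(pan[["gIndex"]], 0)
  expect_true(is.na(pan[["GlobalShrinkageFactor"]]))
  expect_true(is.na(pan[["E_abMean"]]))
  expect_true(is.na(pan[["E_01Mean"]]))
})

test_that("panel of a well-specified model is near mean calibration", {
  spec <- tiny_uni_spec(n_total = 15000L, beta1 = log(3), seed = 55L)
  ds <- make_dataset(spec, 1)
  fit <- fit_logistic(ds$train_X[, "x1", drop = FALSE], ds$train_y)
  pan <- measure_panel(predict_risk(fit, ds$test_X, y = ds$test_y))
  expect_lt(abs(pan[["OR_caliLarge"]] - 1), 0.15)
  expect_lt(abs(pan[["U"]]), 0.005)
  expect_equal(pan[["Dxy"]], 2 * (pan[["AUC"]] - 0.5), tolerance = 1e-12)
  expect_equal(pan[["Q"]], pan[["D"]] - pan[["U"]], tolerance = 1e-12)
  expect_equal(pan[["IDI_diff1"]], pan[["R2_Tjur"]], tolerance = 1e-10)
})
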
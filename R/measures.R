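#' Names of the 25-measure performance panel
#'
#' Row labels of the summary tables, in canonical order: discrimination
#' (AUC, Dxy, gIndex), calibration (U, D, Q, calibration-in-the-large odds
#' ratio, logistic-calibration and LOWESS error families), and overall
#' performance (Brier score, nine pseudo R-squares, global shrinkage
#' factor, IDI against the null model).
#'
#' @export
MEASURE_NAMES <- c(
  "AUC", "Dxy", "gIndex", "U", "D", "Q", "OR_caliLarge",
  "Emax_ab", "E_abMean", "Emax_01", "E_01Mean",
  "Eavg_LOWESS", "ECI_LOWESS", "brierScore",
  "R2_Nagelkerke", "R2_McFadden", "R2_McFaddenAdj", "R2_CoxSnell",
  "R2_AldrichNelson", "R2_VeallZimmermann", "R2_Efron",
  "R2_McKelveyZavoina", "R2_Tjur", "GlobalShrinkageFactor", "IDI_diff1"
)

#' C statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen event subject receives a higher
#' predicted risk than a randomly chosen non-event subject, ties counted
#' one half. Computed by the rank identity (O(n log n)), which equals the
#' brute-force count over all event/non-event pairs.
#'
#' @param p predicted risks.
#' @param y observed 0/1 outcomes.
#' @return the C statistic, or `NA` if only one class is present.
#' @export
c_statistic <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)  # mid-ranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Somers' Dxy rank correlation
#'
#' `Dxy = 2 (C - 0.5)`.
#'
#' @inheritParams c_statistic
#' @return Somers' Dxy, or `NA` if only one class is present.
#' @export
somers_dxy <- function(p, y) {
  2 * (c_statistic(p, y) - 0.5)
}

#' g-index (Gini mean difference of the linear predictor)
#'
#' Mean absolute difference of the linear predictor over all unordered
#' pairs, computed via the sorted-order identity
#' `sum_i (2i - n - 1) x_(i) / choose(n, 2)`.
#'
#' @param lp linear predictor (log-odds) values, length >= 2.
#' @return the Gini mean difference.
#' @export
g_index <- function(lp) {
  n <- length(lp)
  stopifnot(n >= 2)
  s <- sort(lp)
  sum((2 * seq_len(n) - n - 1) * s) / (n * (n - 1) / 2)
}

#' Logistic recalibration of predicted risks
#'
#' Fits `logit P(y = 1) = a + b logit(p)` by maximum likelihood on the test
#' set. A well calibrated model has `(a, b)` near `(0, 1)`. When the
#' predictions are constant the slope is inestimable: an intercept-only
#' model is fitted and the result flagged `degenerate`.
#'
#' @inheritParams c_statistic
#' @return an object of class `calib_fit` with the recalibration intercept
#'   `a_hat` and slope `b_hat`, the log-likelihoods of the free fit, of the
#'   identity calibration `(a, b) = (0, 1)` (i.e. of `p` itself), and of
#'   the test intercept-only (null) model, plus the `degenerate` flag.
#' @export
logistic_recalibration <- function(p, y) {
  p <- clip_prob(p)
  x <- logit(p)
  ll_at <- function(q) sum(y * log(q) + (1 - y) * log(1 - q))
  ll_identity <- ll_at(p)
  ll_null <- ll_at(mean(y))
  if (stats::sd(x) == 0) {
    return(structure(list(a_hat = logit(mean(y)), b_hat = NA_real_,
                          loglik_free = ll_null,
                          loglik_identity = ll_identity,
                          loglik_null = ll_null, degenerate = TRUE),
                     class = "calib_fit"))
  }
  fit <- stats::glm(y ~ x, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  structure(list(a_hat = unname(stats::coef(fit)[1]),
                 b_hat = unname(stats::coef(fit)[2]),
                 loglik_free = ll_at(clip_prob(stats::fitted(fit))),
                 loglik_identity = ll_identity,
                 loglik_null = ll_null, degenerate = FALSE),
            class = "calib_fit")
}

#' Unreliability, discrimination and quality indices (U, D, Q)
#'
#' Validation-probability indices derived from likelihood-ratio statistics
#' of the logistic recalibration: with `chi2_D = 2 (loglik_free -
#' loglik_null)`, `D = (chi2_D - 1) / n`; with `chi2_U = 2 (loglik_free -
#' loglik_identity)`, `U = (chi2_U - 2) / n` (one parameter fewer is
#' subtracted in the degenerate constant-prediction case); `Q = D - U`
#' exactly.
#'
#' @param calib a [logistic_recalibration()] result.
#' @param n test-set size the calibration was computed on.
#' @return named numeric vector `c(U, D, Q)`.
#' @export
udq_indices <- function(calib, n) {
  chi2_D <- 2 * (calib$loglik_free - calib$loglik_null)
  chi2_U <- 2 * (calib$loglik_free - calib$loglik_identity)
  D <- (chi2_D - 1) / n
  U <- (chi2_U - (if (calib$degenerate) 1 else 2)) / n
  c(U = U, D = D, Q = D - U)
}

#' Calibration-in-the-large odds ratio
#'
#' Ratio of predicted odds to observed outcome odds,
#' `odds(mean p) / odds(mean y)`; 1 indicates mean calibration.
#'
#' @inheritParams c_statistic
#' @return the odds ratio, or `NA` when the observed rate is 0 or 1.
#' @export
calibration_large_or <- function(p, y) {
  obs <- mean(y)
  if (obs <= 0 || obs >= 1) return(NA_real_)
  pred <- mean(p)
  (pred / (1 - pred)) / (obs / (1 - obs))
}

#' Logistic-calibration error family (Emax / E-mean)
#'
#' From the recalibration curve `c(q) = expit(a + b logit(q))` the error at
#' a predicted risk `q` is `e(q) = |q - c(q)|`. The `_ab` pair evaluates
#' `e` over the observed predictions (whose range is `[min p, max p]`);
#' the `_01` pair evaluates it on a fixed grid of risks from 0.001 to
#' 0.999 in steps of 0.001. For degenerate (constant) predictions the
#' curve collapses to the observed rate: the means are reported missing and
#' the maxima equal `|p - observed rate|`.
#'
#' @inheritParams c_statistic
#' @param calib optional precomputed [logistic_recalibration()] fit.
#' @return named numeric vector
#'   `c(Emax_ab, E_abMean, Emax_01, E_01Mean)`.
#' @export
calibration_errors_logistic <- function(p, y,
                                        calib = logistic_recalibration(p, y)) {
  p <- clip_prob(p)
  if (calib$degenerate) {
    e0 <- abs(p[1] - mean(y))
    return(c(Emax_ab = e0, E_abMean = NA_real_,
             Emax_01 = e0, E_01Mean = NA_real_))
  }
  curve <- function(q) expit(calib$a_hat + calib$b_hat * logit(q))
  e_obs <- abs(p - curve(p))
  grid <- seq(0.001, 0.999, by = 0.001)
  e_grid <- abs(grid - curve(grid))
  c(Emax_ab = max(e_obs), E_abMean = mean(e_obs),
    Emax_01 = max(e_grid), E_01Mean = mean(e_grid))
}

#' LOWESS calibration errors (Eavg, ECI)
#'
#' Smooths the observed outcomes on the predicted risks with a locally
#' weighted scatterplot smoother (span 2/3, zero robustness iterations) to
#' obtain a nonparametric calibration curve `c_i` at every subject, then
#' reports the average absolute error `Eavg = mean |p_i - c_i|` and the
#' estimated calibration index `ECI = 100 mean (p_i - c_i)^2`. Constant
#' predictions fall back to the observed event rate as the curve.
#'
#' @inheritParams c_statistic
#' @return named numeric vector `c(Eavg_LOWESS, ECI_LOWESS)`.
#' @export
lowess_calibration <- function(p, y) {
  stopifnot(length(p) >= 10)
  if (stats::sd(p) == 0) {
    chat <- rep(mean(y), length(p))
  } else {
    lw <- stats::lowess(p, y, f = 2 / 3, iter = 0)
    chat <- stats::approx(lw$x, lw$y, xout = p, rule = 2, ties = mean)$y
  }
  c(Eavg_LOWESS = mean(abs(p - chat)),
    ECI_LOWESS = 100 * mean((p - chat)^2))
}

#' Brier score
#'
#' Mean squared difference between predicted risk and observed outcome.
#'
#' @inheritParams c_statistic
#' @return the Brier score.
#' @export
brier_score <- function(p, y) mean((p - y)^2)

#' The nine pseudo R-squared measures
#'
#' Computed from the test-set predictions: with
#' `Lm = sum(y log p + (1 - y) log(1 - p))`, `L0` the log-likelihood at the
#' observed event rate, `chi2 = 2 (Lm - L0)` and `k` the number of
#' non-intercept terms of the candidate:
#' Cox-Snell `1 - exp(-chi2/n)`; Nagelkerke scales Cox-Snell by its
#' attainable maximum; McFadden `1 - Lm/L0` and its `k`-adjusted variant;
#' Aldrich-Nelson `chi2/(chi2 + n)`; Veall-Zimmermann rescales
#' Aldrich-Nelson by `(n - 2 L0)/(-2 L0)`; Efron is one minus the squared
#' error ratio; McKelvey-Zavoina is the latent-scale variance ratio
#' `var(logit p) / (var(logit p) + pi^2/3)`; Tjur is the discrimination
#' slope `mean(p | y = 1) - mean(p | y = 0)`.
#'
#' @inheritParams c_statistic
#' @param k number of non-intercept predictor terms of the candidate model
#'   (0 for the flip-coin reference).
#' @return named numeric vector of the nine pseudo R-squares.
#' @export
pseudo_r2_panel <- function(p, y, k = 0) {
  p <- clip_prob(p)
  n <- length(y)
  if (length(unique(y)) < 2L) {
    return(stats::setNames(rep(NA_real_, 9),
                           c("R2_Nagelkerke", "R2_McFadden", "R2_McFaddenAdj",
                             "R2_CoxSnell", "R2_AldrichNelson",
                             "R2_VeallZimmermann", "R2_Efron",
                             "R2_McKelveyZavoina", "R2_Tjur")))
  }
  Lm <- sum(y * log(p) + (1 - y) * log(1 - p))
  p0 <- mean(y)
  L0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  chi2 <- 2 * (Lm - L0)
  cox_snell <- 1 - exp(-chi2 / n)
  v <- stats::var(logit(p))
  c(R2_Nagelkerke = cox_snell / (1 - exp(2 * L0 / n)),
    R2_McFadden = 1 - Lm / L0,
    R2_McFaddenAdj = 1 - (Lm - k) / L0,
    R2_CoxSnell = cox_snell,
    R2_AldrichNelson = chi2 / (chi2 + n),
    R2_VeallZimmermann = (chi2 / (chi2 + n)) * (n - 2 * L0) / (-2 * L0),
    R2_Efron = 1 - sum((y - p)^2) / sum((y - p0)^2),
    R2_McKelveyZavoina = v / (v + pi^2 / 3),
    R2_Tjur = mean(p[y == 1]) - mean(p[y == 0]))
}

#' Integrated discrimination improvement
#'
#' Difference of discrimination slopes: `IDI = slope(p) - slope(p_ref)`
#' where the discrimination slope is `mean(p | y = 1) - mean(p | y = 0)`.
#' Against the null reference (constant observed rate) the IDI equals the
#' Tjur R-squared analytically.
#'
#' @param p predicted risks of the model under evaluation.
#' @param p_ref predicted risks of the reference model; defaults to the
#'   null model (constant observed rate).
#' @param y observed 0/1 outcomes, shared by both prediction vectors.
#' @return the IDI, or `NA` if only one class is present.
#' @export
idi <- function(p, p_ref = rep(mean(y), length(y)), y) {
  if (length(unique(y)) < 2L) return(NA_real_)
  slope <- function(q) mean(q[y == 1]) - mean(q[y == 0])
  slope(p) - slope(p_ref)
}

#' Compute the full 25-measure panel for one prediction set
#'
#' Populates every slot of the panel from the test-set predictions; the
#' global shrinkage factor is taken from the candidate's training fit and
#' is missing for the flip-coin reference. Individual measure failures are
#' recorded as missing values, never as a panel failure.
#'
#' @param pred a `prediction_set` with observed outcomes attached.
#' @return a named numeric vector of class `measure_panel` with the 25
#'   entries of [MEASURE_NAMES].
#' @export
measure_panel <- function(pred) {
  stopifnot(inherits(pred, "prediction_set"), !is.null(pred$y))
  p <- pred$p_hat
  y <- pred$y
  k <- if (is.null(pred$model)) 0 else pred$model$df_model
  safe <- function(expr) {
    tryCatch(expr, error = function(e) NA_real_,
             warning = function(w) suppressWarnings(expr))
  }
  calib <- safe(logistic_recalibration(p, y))
  udq <- if (inherits(calib, "calib_fit")) {
    udq_indices(calib, length(y))
  } else c(U = NA_real_, D = NA_real_, Q = NA_real_)
  emax <- if (inherits(calib, "calib_fit")) {
    safe(calibration_errors_logistic(p, y, calib))
  } else rep(NA_real_, 4)
  if (length(emax) != 4) emax <- rep(NA_real_, 4)
  low <- safe(lowess_calibration(p, y))
  if (length(low) != 2) low <- rep(NA_real_, 2)
  out <- c(
    AUC = safe(c_statistic(p, y)),
    Dxy = safe(somers_dxy(p, y)),
    gIndex = safe(g_index(pred$lp)),
    udq,
    OR_caliLarge = safe(calibration_large_or(p, y)),
    Emax_ab = emax[[1]], E_abMean = emax[[2]],
    Emax_01 = emax[[3]], E_01Mean = emax[[4]],
    Eavg_LOWESS = low[[1]], ECI_LOWESS = low[[2]],
    brierScore = safe(brier_score(p, y)),
    pseudo_r2_panel(p, y, k),
    GlobalShrinkageFactor = heuristic_shrinkage(pred$model),
    IDI_diff1 = safe(idi(p, y = y))
  )
  structure(out[MEASURE_NAMES], class = "measure_panel")
}

#' @export
print.measure_panel <- function(x, ...) {
  cat("<measure_panel> (25 measures)\n")
  print(round(unclass(x), 4))
  invisible(x)
}
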
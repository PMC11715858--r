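#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around the iteratively reweighted least squares fit of
#' [stats::glm()] that records what the candidate machinery needs: the
#' coefficient vector, model degrees of freedom, and the training
#' likelihood-ratio chi-square against the intercept-only model (the input
#' of the heuristic shrinkage factor). Diverging coefficients (complete or
#' quasi-complete separation) are capped at +/- 15 and flagged
#' `converged = FALSE`; the log-likelihoods are then recomputed at the
#' capped coefficients so every downstream measure stays finite.
#'
#' @param X data frame of predictors (zero columns gives the intercept-only
#'   model).
#' @param y 0/1 outcome vector with both classes present.
#' @return an object of class `fitted_logistic`.
#' @export
fit_logistic <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(length(unique(y)) == 2L)
  if (ncol(X) == 0L) {
    coefs <- c("(Intercept)" = logit(mean(y)))
    converged <- TRUE
  } else {
    dat <- cbind(data.frame(y = y), X)
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10,
                                                   maxit = 100))
    coefs <- stats::coef(fit)
    if (anyNA(coefs)) {
      warning("aliased (collinear) columns dropped: ",
              paste(names(coefs)[is.na(coefs)], collapse = ", "))
      coefs <- coefs[!is.na(coefs)]
    }
    converged <- isTRUE(fit$converged)
    if (any(abs(coefs) > 15)) {
      coefs <- pmin(pmax(coefs, -15), 15)
      converged <- FALSE
    }
  }
  new_fitted_logistic(coefs, X, y, converged)
}

# Assemble a fitted_logistic from a coefficient vector (intercept first),
# recomputing training log-likelihoods at those coefficients.
new_fitted_logistic <- function(coefs, X, y, converged = TRUE) {
  vars <- setdiff(names(coefs), "(Intercept)")
  lp <- rep(coefs[["(Intercept)"]], length(y))
  if (length(vars)) {
    lp <- lp + drop(as.matrix(X[, vars, drop = FALSE]) %*% coefs[vars])
  }
  p <- clip_prob(expit(lp))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  structure(list(
    variable_names = vars,
    coefficients = coefs,
    df_model = length(vars),
    train_loglik = ll,
    train_null_loglik = ll0,
    train_lr_chi2 = max(0, 2 * (ll - ll0)),
    converged = converged
  ), class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat("<fitted_logistic>", if (!x$converged) "(not converged)", "\n")
  print(round(x$coefficients, 4))
  cat("  df:", x$df_model,
      "| LR chi2:", round(x$train_lr_chi2, 2),
      "| shrinkage factor:",
      round(heuristic_shrinkage(x), 3), "\n")
  invisible(x)
}

#' Predicted risks of a fitted logistic model
#'
#' @param model a [fit_logistic()] result.
#' @param X data frame containing the model's variables.
#' @param y optional observed outcomes to attach (required downstream by the
#'   measure panel).
#' @param candidate optional candidate name label.
#' @return an object of class `prediction_set` with elements `p_hat`
#'   (clipped to (0, 1)), `lp = logit(p_hat)`, `y`, `candidate`, `model`.
#' @export
predict_risk <- function(model, X, y = NULL, candidate = NA_character_) {
  missing_cols <- setdiff(model$variable_names, names(X))
  if (length(missing_cols)) {
    stop("missing column(s) in newdata: ",
         paste(missing_cols, collapse = ", "))
  }
  lp <- rep(model$coefficients[["(Intercept)"]], nrow(X))
  if (length(model$variable_names)) {
    lp <- lp + drop(as.matrix(X[, model$variable_names, drop = FALSE]) %*%
                      model$coefficients[model$variable_names])
  }
  p <- clip_prob(expit(lp))
  structure(list(p_hat = p, lp = logit(p), y = y,
                 candidate = candidate, model = model),
            class = "prediction_set")
}

#' The flip-coin reference model
#'
#' Predicts risk 0.5 for every subject — the no-information reference whose
#' C statistic is 0.5 and Brier score 0.25 for any outcome vector. No
#' fitted model is attached, so training-based measures (the shrinkage
#' factor) are missing for it.
#'
#' @param n number of subjects.
#' @param y optional observed outcomes to attach.
#' @return a `prediction_set` with constant `p_hat = 0.5`.
#' @export
flip_coin_model <- function(n, y = NULL) {
  stopifnot(n >= 1)
  structure(list(p_hat = rep(0.5, n), lp = rep(0, n), y = y,
                 candidate = "FlipCoin", model = NULL),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set>", x$candidate, "|", length(x$p_hat), "subjects\n")
  cat("  mean predicted risk:", round(mean(x$p_hat), 4))
  if (!is.null(x$y)) cat(" | observed rate:", round(mean(x$y), 4))
  cat("\n")
  invisible(x)
}

#' Bidirectional stepwise AIC selection
#'
#' Starts from the logistic model containing all pool and forced-in columns
#' and searches both directions for the minimum-AIC model
#' (`AIC = -2 loglik + 2 (df + 1)`), never adding excluded columns.
#' Variables are ordered by name so ties break deterministically. The
#' search may remove every variable and return the intercept-only model.
#'
#' @param train_X training predictor table.
#' @param train_y training 0/1 outcomes.
#' @param pool columns eligible for selection.
#' @param forced_out columns excluded from the search entirely.
#' @return a `fitted_logistic` of the selected model.
#' @export
stepwise_aic <- function(train_X, train_y, pool, forced_out = character()) {
  pool <- sort(setdiff(pool, forced_out))
  if (!length(pool)) stop("empty variable pool after exclusions")
  dat <- cbind(data.frame(y = train_y), train_X[, pool, drop = FALSE])
  full <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  sel <- MASS::stepAIC(full, direction = "both",
                       scope = list(lower = ~1, upper = stats::formula(full)),
                       trace = 0)
  keep <- setdiff(names(stats::coef(sel)), "(Intercept)")
  fit_logistic(train_X[, keep, drop = FALSE], train_y)
}

#' Heuristic (global) shrinkage factor
#'
#' `gamma = (LR chi2 - df) / LR chi2` from the training fit — van Houwelingen
#' and le Cessie's heuristic estimate of how much fitted coefficients are
#' expected to be overfitted. At most 1 by construction; negative for
#' near-null fits; missing when the model chi-square is zero or no model is
#' attached (flip-coin).
#'
#' @param model a `fitted_logistic`, or `NULL`.
#' @return a single numeric, possibly `NA`.
#' @export
heuristic_shrinkage <- function(model) {
  if (is.null(model) || model$df_model < 1L) return(NA_real_)
  if (model$train_lr_chi2 <= 0) return(NA_real_)
  (model$train_lr_chi2 - model$df_model) / model$train_lr_chi2
}

#' Apply heuristic shrinkage to a fitted model
#'
#' Multiplies the non-intercept coefficients by the heuristic shrinkage
#' factor and re-estimates the intercept by a one-parameter logistic fit
#' with the shrunken linear predictor as a fixed offset on the training
#' data. The returned model's training statistics are recomputed at the
#' shrunken coefficients.
#'
#' @param model a [fit_logistic()] result.
#' @param train_X,train_y the training data the model was fitted on.
#' @return a `fitted_logistic` with shrunken coefficients.
#' @export
shrink_model <- function(model, train_X, train_y) {
  gamma <- heuristic_shrinkage(model)
  if (is.na(gamma)) {
    warning("shrinkage factor undefined; returning model unchanged")
    return(model)
  }
  slopes <- gamma * model$coefficients[model$variable_names]
  off <- drop(as.matrix(train_X[, model$variable_names, drop = FALSE]) %*%
                slopes)
  refit <- stats::glm(train_y ~ 1, offset = off, family = stats::binomial())
  coefs <- c("(Intercept)" = unname(stats::coef(refit)[1]), slopes)
  new_fitted_logistic(coefs, train_X, train_y, converged = model$converged)
}
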
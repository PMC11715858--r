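#' Declare a candidate model
#'
#' A candidate is a named recipe for producing test-set predictions from a
#' simulated dataset: a plain logistic fit on given columns, a
#' stepwise-AIC selection over a pool, a heuristically shrunken fit, or the
#' flip-coin reference.
#'
#' @param name report label of the candidate (e.g. `"AddIndModel"`).
#' @param variables columns of the fitted model (for `none` / `shrink`).
#' @param transform one of `"none"`, `"stepAIC"`, `"shrink"`, `"flip-coin"`.
#' @param pool columns eligible for stepwise selection.
#' @param forced_out columns the candidate may never contain.
#' @return an object of class `candidate_spec`.
#' @export
candidate_spec <- function(name, variables = character(),
                           transform = c("none", "stepAIC", "shrink",
                                         "flip-coin"),
                           pool = character(), forced_out = character()) {
  transform <- match.arg(transform)
  if (transform == "flip-coin" && (length(variables) || length(pool))) {
    stop("the flip-coin candidate has no variables")
  }
  if (length(intersect(pool, forced_out)) &&
      transform != "stepAIC") {
    stop("pool and forced_out overlap")
  }
  structure(list(name = name, variables = variables, transform = transform,
                 pool = pool, forced_out = forced_out),
            class = "candidate_spec")
}

#' The univariate candidate catalog (10 models)
#'
#' `TrueModel` (the causal predictor alone), `FlipCoin`, the true model plus
#' one independent (`AddIndModel`) or correlated (`Add03Model`,
#' `Add05Model`, `Add08Model`) proxy, stepwise-AIC selection over causal
#' plus all proxies with the causal variable included (`AICTrueModel`) or
#' excluded (`AICAddModel`) before the procedure, and heuristically
#' shrunken versions of the true (`ShrinkTrueModel`) and all-proxy
#' (`ShrinkAddModel`) fits.
#'
#' @param proxy_corrs correlations of the generated proxies (defines the
#'   `AddXXModel` entries).
#' @return named list of [candidate_spec()] objects.
#' @export
univariate_catalog <- function(proxy_corrs = c(0.3, 0.5, 0.8)) {
  corr_cols <- vapply(proxy_corrs, proxy_label, "")
  proxies <- c("proxy_ind", corr_cols)
  specs <- c(
    list(candidate_spec("TrueModel", "x1"),
         candidate_spec("FlipCoin", transform = "flip-coin"),
         candidate_spec("AddIndModel", c("x1", "proxy_ind"))),
    lapply(seq_along(proxy_corrs), function(i) {
      candidate_spec(sprintf("Add%02dModel", round(10 * proxy_corrs[i])),
                     c("x1", corr_cols[i]))
    }),
    list(
      candidate_spec("AICTrueModel", transform = "stepAIC",
                     pool = c("x1", proxies)),
      candidate_spec("ShrinkTrueModel", "x1", transform = "shrink"),
      candidate_spec("AICAddModel", transform = "stepAIC",
                     pool = proxies, forced_out = "x1"),
      candidate_spec("ShrinkAddModel", proxies, transform = "shrink")
    )
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' The multivariate candidate catalog (12 models)
#'
#' True two-predictor model, flip-coin, the single-causal submodels
#' (`Variable1`, `Variable2`), the true model plus one extra variable
#' (independent continuous, correlated continuous, or categorical), and the
#' missing-variable-1 group in which the first causal predictor is dropped
#' and replaced by independent and/or correlated proxies.
#'
#' @param corr_rho which generated proxy correlation the `AddCorr*` entries
#'   use.
#' @return named list of [candidate_spec()] objects.
#' @export
multivariate_catalog <- function(corr_rho = 0.5) {
  c1 <- paste0(proxy_label(corr_rho), "_x1")
  c2 <- paste0(proxy_label(corr_rho), "_x2")
  specs <- list(
    candidate_spec("TrueModel", c("x1", "x2")),
    candidate_spec("FlipCoin", transform = "flip-coin"),
    candidate_spec("Variable1", "x1"),
    candidate_spec("Variable2", "x2"),
    candidate_spec("AddIndCont", c("x1", "x2", "proxy_ind_cont")),
    candidate_spec("AddCorrCont", c("x1", "x2", c1)),
    candidate_spec("AddCat", c("x1", "x2", "proxy_ind_cat")),
    candidate_spec("AddIndVar1", c("proxy_ind_cont", "x2")),
    candidate_spec("AddCorrVar1", c(c1, "x2")),
    candidate_spec("AddCorrVar2", c(c2, "x2")),
    candidate_spec("AddIndCorrVar1", c("proxy_ind_cont", c1, "x2")),
    candidate_spec("AddCorrVar1AddCorrVar2", c(c1, c2, "x2"))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

default_catalog <- function(arity, proxy_corrs = c(0.3, 0.5, 0.8)) {
  if (arity == "univariate") univariate_catalog(proxy_corrs)
  else multivariate_catalog()
}

#' Fit every catalog candidate on one dataset
#'
#' Trains each candidate on the training part and predicts on the test
#' part, returning one `prediction_set` per catalog entry. The `TrueModel`
#' entry uses exactly the causal columns.
#'
#' @param dataset a [make_dataset()] result.
#' @param catalog optional list of [candidate_spec()]; defaults to the
#'   catalog matching the dataset's arity.
#' @return named list of `prediction_set` objects, in catalog order.
#' @export
build_candidates <- function(dataset, catalog = NULL) {
  if (is.null(catalog)) {
    catalog <- default_catalog(dataset$spec$arity, dataset$spec$proxy_corrs)
  }
  available <- names(dataset$train_X)
  out <- lapply(catalog, function(cs) {
    need <- setdiff(c(cs$variables, cs$pool), cs$forced_out)
    if (length(setdiff(need, available))) {
      stop("candidate ", cs$name, " needs missing column(s): ",
           paste(setdiff(need, available), collapse = ", "))
    }
    if (cs$transform == "flip-coin") {
      return(flip_coin_model(length(dataset$test_y), dataset$test_y))
    }
    model <- switch(cs$transform,
      none = fit_logistic(dataset$train_X[, cs$variables, drop = FALSE],
                          dataset$train_y),
      shrink = shrink_model(
        fit_logistic(dataset$train_X[, cs$variables, drop = FALSE],
                     dataset$train_y),
        dataset$train_X, dataset$train_y),
      stepAIC = stepwise_aic(dataset$train_X, dataset$train_y,
                             pool = cs$pool, forced_out = cs$forced_out)
    )
    predict_risk(model, dataset$test_X, y = dataset$test_y,
                 candidate = cs$name)
  })
  for (nm in names(out)) out[[nm]]$candidate <- nm
  out
}
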
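#' Construct a simulation scenario
#'
#' A scenario is one point of the simulation grid: it fixes the
#' outcome-generating ("true") logistic model — intercept, log-odds effects,
#' predictor kinds — together with the proxy-predictor correlations, the
#' sample size, the train/test split and the number of Monte-Carlo
#' replicates.
#'
#' @param scenario_id opaque label for the scenario.
#' @param arity `"univariate"` (one causal predictor) or `"multivariate"`
#'   (two causal predictors).
#' @param predictor_kinds character vector (`"continuous"` / `"binary"`),
#'   one entry per causal predictor.
#' @param beta0 intercept of the true model on the log-odds scale.
#' @param betas log-odds effects of the causal predictors; same length as
#'   `predictor_kinds`.
#' @param interaction_beta optional log-odds coefficient of the product of
#'   the two causal predictors (multivariate only); `NULL` for none.
#' @param binary_prevalence Bernoulli prevalence used for every binary
#'   predictor (causal or proxy), in (0, 1).
#' @param causal_corr target Pearson correlation between the two causal
#'   predictors (multivariate only), in `[0, 1)`.
#' @param proxy_corrs target correlations of the correlated proxy
#'   predictors, each in `[0, 1)`.
#' @param n_total total sample size before the train/test split.
#' @param train_fraction fraction of rows assigned to the training set.
#' @param n_reps number of replicate datasets for this scenario.
#' @param seed integer seed of the scenario's random substream.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, arity, predictor_kinds, beta0, betas,
                          interaction_beta = NULL,
                          binary_prevalence = 0.5, causal_corr = 0,
                          proxy_corrs = c(0.3, 0.5, 0.8),
                          n_total = if (arity == "univariate") 15000L else 3000L,
                          train_fraction = 0.8, n_reps = 100L, seed = 1L) {
  arity <- match.arg(arity, c("univariate", "multivariate"))
  predictor_kinds <- match.arg(predictor_kinds, c("continuous", "binary"),
                               several.ok = TRUE)
  if (length(betas) != length(predictor_kinds)) {
    stop("`betas` and `predictor_kinds` must have the same length")
  }
  n_causal <- if (arity == "univariate") 1L else 2L
  if (length(predictor_kinds) != n_causal) {
    stop(arity, " scenarios need exactly ", n_causal, " predictor kind(s)")
  }
  if (binary_prevalence <= 0 || binary_prevalence >= 1) {
    stop("`binary_prevalence` must lie strictly inside (0, 1)")
  }
  if (causal_corr < 0 || causal_corr >= 1) {
    stop("`causal_corr` must lie in [0, 1)")
  }
  if (any(proxy_corrs < 0 | proxy_corrs >= 1)) {
    stop("`proxy_corrs` must lie in [0, 1)")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly inside (0, 1)")
  }
  if (any(betas < log(1) - 1e-12 | betas > log(4) + 1e-12)) {
    warning("beta outside the default [log 1, log 4] grid range; ",
            "scenario flagged non-default", call. = FALSE)
  }
  structure(list(
    scenario_id = as.character(scenario_id),
    arity = arity,
    predictor_kinds = predictor_kinds,
    beta0 = beta0,
    betas = betas,
    interaction_beta = interaction_beta,
    binary_prevalence = binary_prevalence,
    causal_corr = causal_corr,
    proxy_corrs = proxy_corrs,
    n_total = as.integer(n_total),
    train_fraction = train_fraction,
    n_reps = as.integer(n_reps),
    seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$scenario_id, "\n")
  cat("  arity:", x$arity,
      "| kinds:", paste(x$predictor_kinds, collapse = "+"), "\n")
  cat("  beta0:", format(x$beta0, digits = 3),
      "| betas:", paste(format(x$betas, digits = 3), collapse = ", "))
  if (!is.null(x$interaction_beta)) {
    cat(" | interaction:", format(x$interaction_beta, digits = 3))
  }
  cat("\n  n:", x$n_total, "| train:", x$train_fraction,
      "| reps:", x$n_reps, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Default univariate grid configuration
#'
#' Factor levels reconstructing the univariate scenario grid: effect sizes
#' spanning log(1) to log(4), four baseline risks, continuous and binary
#' causal predictors, two binary prevalences.
#'
#' @param n_reps replicates per scenario.
#' @param seed master seed of the grid.
#' @return a grid configuration list for [build_grid()].
#' @export
default_univariate_config <- function(n_reps = 100L, seed = 20260101L) {
  list(
    arity = "univariate",
    beta1 = log(c(1, 1.3, 1.7, 2, 2.5, 3, 4)),
    beta0 = logit(c(0.1, 0.2, 0.3, 0.5)),
    predictor_kinds = c("continuous", "binary"),
    binary_prevalence = c(0.3, 0.5),
    proxy_corrs = c(0.3, 0.5, 0.8),
    n_total = 15000L,
    train_fraction = 0.8,
    n_reps = n_reps,
    seed = seed
  )
}

#' Default multivariate grid configuration
#'
#' Two causal predictors (both continuous, or one continuous and one
#' binary), both with non-null effects, optionally correlated with each
#' other.
#'
#' @inheritParams default_univariate_config
#' @return a grid configuration list for [build_grid()].
#' @export
default_multivariate_config <- function(n_reps = 100L, seed = 20260102L) {
  list(
    arity = "multivariate",
    beta1 = log(c(1.3, 1.7, 2, 2.5, 3, 4)),
    beta2 = log(c(1.3, 1.7, 2, 2.5, 3, 4)),
    beta0 = logit(c(0.1, 0.2, 0.3, 0.5)),
    predictor_kinds = list(c("continuous", "continuous"),
                           c("continuous", "binary")),
    binary_prevalence = c(0.3, 0.5),
    causal_corr = c(0, 0.3, 0.5),
    proxy_corrs = c(0.3, 0.5, 0.8),
    n_total = 3000L,
    train_fraction = 0.8,
    n_reps = n_reps,
    seed = seed
  )
}

#' Materialise a scenario grid from factor levels
#'
#' Expands the Cartesian product of the configured factor levels into a list
#' of [scenario_spec()] objects, each with a deterministic seed derived from
#' the master seed and its grid position, so that grids parallelise without
#' seed collisions and two builds from the same configuration are identical.
#'
#' @param config a configuration list as returned by
#'   [default_univariate_config()] / [default_multivariate_config()]: factor
#'   levels `beta1`, `beta0`, `predictor_kinds` (plus `beta2`,
#'   `causal_corr` for multivariate, `binary_prevalence` when a binary
#'   predictor can occur) and scalars `proxy_corrs`, `n_total`,
#'   `train_fraction`, `n_reps`, `seed`.
#' @return a list of `scenario_spec` objects; length equals the product of
#'   the level counts.
#' @export
build_grid <- function(config) {
  arity <- match.arg(config$arity, c("univariate", "multivariate"))
  levels <- list(
    beta1 = config$beta1,
    beta0 = config$beta0,
    kind_idx = seq_along(config$predictor_kinds)
  )
  if (arity == "multivariate") {
    levels$beta2 <- config$beta2
    levels$causal_corr <- if (is.null(config$causal_corr)) 0 else config$causal_corr
  }
  levels$binary_prevalence <-
    if (is.null(config$binary_prevalence)) 0.5 else config$binary_prevalence
  if (any(lengths(levels) == 0)) {
    stop("empty factor level list in grid configuration: ",
         paste(names(levels)[lengths(levels) == 0], collapse = ", "))
  }
  cells <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  prefix <- if (arity == "univariate") "uni" else "mul"
  specs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, , drop = FALSE]
    kinds <- config$predictor_kinds[[row$kind_idx]]
    betas <- if (arity == "univariate") row$beta1 else c(row$beta1, row$beta2)
    specs[[i]] <- scenario_spec(
      scenario_id = sprintf("%s_%04d", prefix, i),
      arity = arity,
      predictor_kinds = kinds,
      beta0 = row$beta0,
      betas = betas,
      binary_prevalence = row$binary_prevalence,
      causal_corr = if (arity == "multivariate") row$causal_corr else 0,
      proxy_corrs = if (is.null(config$proxy_corrs)) c(0.3, 0.5, 0.8) else config$proxy_corrs,
      n_total = config$n_total,
      train_fraction = config$train_fraction,
      n_reps = config$n_reps,
      seed = derive_seed(config$seed, i)
    )
  }
  specs
}

#' Read a grid configuration from a YAML file
#'
#' @param path path to a YAML file whose keys mirror the fields of
#'   [default_univariate_config()].
#' @return a grid configuration list.
#' @export
read_grid_config <- function(path) {
  config <- yaml::read_yaml(path)
  if (!is.null(config$predictor_kinds) && config$arity == "multivariate") {
    config$predictor_kinds <- lapply(config$predictor_kinds, unlist)
  }
  config
}
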
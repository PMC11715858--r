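#' Simulate the causal predictors of a scenario
#'
#' Continuous causal predictors are standard Gaussian; binary ones are
#' Bernoulli with the scenario's prevalence. For a multivariate scenario
#' with `causal_corr > 0` the pair is drawn from a Gaussian copula whose
#' latent correlation is solved so that the observed-scale Pearson
#' correlation matches the target (binary margins thresholded at the
#' prevalence quantile).
#'
#' @param spec a [scenario_spec()].
#' @param n number of rows (>= 2).
#' @return a data frame with columns `x1` (and `x2` for multivariate).
#' @export
simulate_predictors <- function(spec, n) {
  stopifnot(n >= 2)
  p <- spec$binary_prevalence
  kinds <- spec$predictor_kinds
  k <- length(kinds)
  if (k == 1L || spec$causal_corr == 0) {
    cols <- lapply(kinds, function(kind) {
      if (kind == "continuous") stats::rnorm(n) else stats::rbinom(n, 1, p)
    })
  } else {
    margin <- if (all(kinds == "continuous")) "cc"
              else if (all(kinds == "binary")) "bb" else "cb"
    r <- solve_latent_corr(spec$causal_corr, margin, p1 = p, p2 = p)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    thresh <- stats::qnorm(1 - p)
    to_margin <- function(z, kind) {
      if (kind == "continuous") z else as.numeric(z > thresh)
    }
    # for "cb" the binary margin must be the one the threshold applies to;
    # kinds are ordered (continuous first in the default grid), and for a
    # binary first margin the construction is symmetric.
    cols <- list(to_margin(z1, kinds[1]), to_margin(z2, kinds[2]))
  }
  names(cols) <- paste0("x", seq_len(k))
  as.data.frame(cols)
}

#' Simulate a proxy predictor with a target correlation
#'
#' Generates a non-causal ("proxy") predictor whose Pearson correlation with
#' an observed target column hits `rho` on the observed scale. A continuous
#' proxy of a continuous target is the classical
#' `rho * z + sqrt(1 - rho^2) * noise` construction on the standardised
#' target. Any construction involving a binary variable goes through a
#' latent Gaussian: the binary target's latent normal is reconstructed by
#' truncated-normal sampling given the observed 0/1 value, the latent
#' correlation is solved numerically so the observed-scale correlation is
#' `rho`, and a binary proxy is thresholded at its prevalence quantile.
#'
#' @param target numeric vector, the observed target column (continuous, or
#'   0/1).
#' @param rho target Pearson correlation in `[0, 1)`; `rho = 0` gives an
#'   independent draw.
#' @param kind kind of the proxy to generate, `"continuous"` or `"binary"`.
#' @param prevalence prevalence of a binary proxy.
#' @return numeric vector of the same length as `target`.
#' @export
simulate_proxy <- function(target, rho, kind = c("continuous", "binary"),
                           prevalence = 0.5) {
  kind <- match.arg(kind)
  n <- length(target)
  if (rho == 0) {
    return(if (kind == "continuous") stats::rnorm(n)
           else stats::rbinom(n, 1, prevalence))
  }
  target_binary <- all(target %in% c(0, 1))
  if (stats::sd(target) == 0) {
    stop("target column is constant; correlation with it is undefined")
  }
  if (target_binary) {
    p_t <- mean(target)
    t_thr <- stats::qnorm(1 - p_t)
    # latent normal of the target, reconstructed by inverse-CDF sampling
    # from the truncated normal implied by the observed 0/1 value
    u <- stats::runif(n)
    z_t <- ifelse(target == 1,
                  stats::qnorm(stats::pnorm(t_thr) + u * (1 - stats::pnorm(t_thr))),
                  stats::qnorm(u * stats::pnorm(t_thr)))
    margin <- if (kind == "binary") "bb" else "cb"
    r <- solve_latent_corr(rho, margin, p1 = prevalence, p2 = p_t)
  } else {
    z_t <- (target - mean(target)) / stats::sd(target)
    margin <- if (kind == "binary") "cb" else "cc"
    r <- solve_latent_corr(rho, margin, p2 = prevalence)
  }
  z <- r * z_t + sqrt(1 - r^2) * stats::rnorm(n)
  if (kind == "binary") as.numeric(z > stats::qnorm(1 - prevalence)) else z
}

#' Simulate binary outcomes from the true logistic model
#'
#' Each outcome is an independent Bernoulli draw with probability
#' `expit(beta0 + sum(beta_k x_k) [+ interaction])`.
#'
#' @param spec a [scenario_spec()].
#' @param predictors data frame containing exactly the causal columns of the
#'   scenario (`x1` and, for multivariate, `x2`).
#' @return integer 0/1 vector of length `nrow(predictors)`.
#' @export
simulate_outcome <- function(spec, predictors) {
  k <- length(spec$betas)
  need <- paste0("x", seq_len(k))
  if (!all(need %in% names(predictors))) {
    stop("predictors must contain columns: ", paste(need, collapse = ", "))
  }
  lp <- spec$beta0 +
    as.matrix(predictors[, need, drop = FALSE]) %*% spec$betas
  if (!is.null(spec$interaction_beta) && k == 2L) {
    lp <- lp + spec$interaction_beta * predictors$x1 * predictors$x2
  }
  stats::rbinom(nrow(predictors), 1, expit(drop(lp)))
}

proxy_label <- function(rho) sprintf("proxy_c%02d", round(10 * rho))

# Append the proxy set for one dataset: one independent proxy per causal
# kind (multivariate always gets a continuous and a categorical independent
# proxy so every catalog entry is supported) plus one correlated proxy per
# configured rho and causal target.
add_proxies <- function(spec, X) {
  p <- spec$binary_prevalence
  meta <- data.frame(column = names(X),
                     role = "causal", rho = NA_real_, target = NA_character_,
                     stringsAsFactors = FALSE)
  add <- function(X, meta, col, values, role, rho = NA_real_, target = NA_character_) {
    X[[col]] <- values
    meta <- rbind(meta, data.frame(column = col, role = role, rho = rho,
                                   target = target, stringsAsFactors = FALSE))
    list(X = X, meta = meta)
  }
  if (spec$arity == "univariate") {
    kind <- spec$predictor_kinds[1]
    res <- add(X, meta, "proxy_ind",
               simulate_proxy(X$x1, 0, kind, p), "proxy-independent")
    for (rho in spec$proxy_corrs) {
      res <- add(res$X, res$meta, proxy_label(rho),
                 simulate_proxy(X$x1, rho, kind, p),
                 "proxy-correlated", rho, "x1")
    }
  } else {
    res <- add(X, meta, "proxy_ind_cont",
               simulate_proxy(X$x1, 0, "continuous"), "proxy-independent")
    res <- add(res$X, res$meta, "proxy_ind_cat",
               simulate_proxy(X$x1, 0, "binary", p), "proxy-independent")
    for (rho in spec$proxy_corrs) {
      for (j in 1:2) {
        tgt <- paste0("x", j)
        kind <- spec$predictor_kinds[j]
        res <- add(res$X, res$meta, paste0(proxy_label(rho), "_", tgt),
                   simulate_proxy(X[[tgt]], rho, kind, p),
                   "proxy-correlated", rho, tgt)
      }
    }
  }
  res
}

#' Generate one replicate dataset of a scenario
#'
#' Composes the three simulation steps — causal predictors, binary outcome
#' from the true model, proxy predictors — then splits the rows 80/20 (or as
#' configured) by a uniform random permutation. Fully reproducible from
#' `(spec$seed, rep_index)`. A split leaving either part without both
#' outcome classes is regenerated from the next substream (at most 100
#' attempts).
#'
#' @param spec a [scenario_spec()].
#' @param rep_index replicate counter, `1 <= rep_index <= spec$n_reps`.
#' @return an object of class `sim_dataset` with elements `train_X`,
#'   `train_y`, `test_X`, `test_y`, `column_meta`, `spec`, `rep_index`.
#' @export
make_dataset <- function(spec, rep_index = 1L) {
  if (rep_index > spec$n_reps) {
    stop("rep_index exceeds the scenario's n_reps")
  }
  for (attempt in seq_len(100L)) {
    set.seed(derive_seed(spec$seed, rep_index, attempt))
    X <- simulate_predictors(spec, spec$n_total)
    y <- simulate_outcome(spec, X)
    res <- add_proxies(spec, X)
    n_train <- floor(spec$n_total * spec$train_fraction)
    idx <- sample.int(spec$n_total)
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
    ok <- function(v) length(unique(v)) == 2L
    if (ok(y[tr]) && ok(y[te])) {
      return(structure(list(
        train_X = res$X[tr, , drop = FALSE],
        train_y = y[tr],
        test_X = res$X[te, , drop = FALSE],
        test_y = y[te],
        column_meta = res$meta,
        spec = spec,
        rep_index = as.integer(rep_index)
      ), class = "sim_dataset"))
    }
  }
  stop("could not generate a split with both outcome classes in train and ",
       "test after 100 attempts (scenario ", spec$scenario_id, ")")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", x$spec$scenario_id, "rep", x$rep_index, "\n")
  cat("  train:", nrow(x$train_X), "rows | test:", nrow(x$test_X), "rows\n")
  cat("  columns:", paste(names(x$train_X), collapse = ", "), "\n")
  cat("  event rate (train):", round(mean(x$train_y), 3), "\n")
  invisible(x)
}

#' Export a simulated dataset as delimited text
#'
#' Writes `<stem>_train` and `<stem>_test` tables (header row, outcome
#' column named `y`).
#'
#' @param dataset a [make_dataset()] result.
#' @param stem path stem for the two output files.
#' @param sep field separator (`","` or `"\t"`).
#' @return invisibly, the two file paths.
#' @export
export_dataset <- function(dataset, stem, sep = ",") {
  ext <- if (sep == ",") ".csv" else ".tsv"
  paths <- paste0(stem, c("_train", "_test"), ext)
  utils::write.table(cbind(y = dataset$train_y, dataset$train_X), paths[1],
                     sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(y = dataset$test_y, dataset$test_X), paths[2],
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
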
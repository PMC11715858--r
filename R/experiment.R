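#' Run all replicates of one scenario
#'
#' For each replicate: generate the dataset, fit every catalog candidate,
#' compute the 25-measure panel per candidate, and difference each
#' candidate's panel against the same replicate's true-model panel
#' (candidate minus true). Fully deterministic given the scenario.
#'
#' @param spec a [scenario_spec()].
#' @param catalog optional candidate catalog (defaults by arity).
#' @param reps optional override of the number of replicates.
#' @return a long data frame of difference records with columns
#'   `scenario_id`, `rep_index`, `candidate`, `measure`, `value`, `diff`.
#'   Replicates that fail are logged and skipped; the scenario errors only
#'   if more than half fail.
#' @export
run_scenario <- function(spec, catalog = NULL, reps = spec$n_reps) {
  if (is.null(catalog)) {
    catalog <- default_catalog(spec$arity, spec$proxy_corrs)
  }
  failures <- 0L
  rep_frames <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_frames[[r]] <- tryCatch({
      ds <- make_dataset(spec, r)
      preds <- build_candidates(ds, catalog)
      panels <- lapply(preds, measure_panel)
      true_panel <- unclass(panels[["TrueModel"]])
      do.call(rbind, lapply(names(panels), function(nm) {
        v <- unclass(panels[[nm]])
        data.frame(scenario_id = spec$scenario_id, rep_index = r,
                   candidate = nm, measure = MEASURE_NAMES,
                   value = unname(v), diff = unname(v - true_panel),
                   stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      message("replicate ", r, " of ", spec$scenario_id,
              " failed: ", conditionMessage(e))
      failures <<- failures + 1L
      NULL
    })
  }
  if (failures > reps / 2) {
    stop("more than half of the replicates of ", spec$scenario_id,
         " failed")
  }
  do.call(rbind, rep_frames)
}

#' Summarise difference records as mean and 95% range
#'
#' Pools all (scenario, replicate) records per candidate and measure and
#' reports the mean and the empirical 2.5th/97.5th percentiles
#' (linear-interpolation quantiles), with missing values excluded. The
#' true-model cell summarises the measure's value itself; every other
#' candidate summarises its difference to the true model, mirroring the
#' report layout.
#'
#' @param records difference records from [run_scenario()].
#' @param true_name candidate whose raw values (not differences) are
#'   summarised.
#' @return a data frame with columns `candidate`, `measure`, `mean`,
#'   `p2.5`, `p97.5`, `n_nonmissing`.
#' @export
summarize_records <- function(records, true_name = "TrueModel") {
  cells <- unique(records[, c("candidate", "measure")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cand <- cells$candidate[i]
    meas <- cells$measure[i]
    sel <- records$candidate == cand & records$measure == meas
    x <- if (cand == true_name) records$value[sel] else records$diff[sel]
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(candidate = cand, measure = meas, mean = NA_real_,
                        p2.5 = NA_real_, p97.5 = NA_real_, n_nonmissing = 0L,
                        stringsAsFactors = FALSE))
    }
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(candidate = cand, measure = meas, mean = mean(x),
               p2.5 = q[1], p97.5 = q[2], n_nonmissing = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a summary as a wide report table
#'
#' One row per measure, one column per candidate, cells formatted
#' `"mean (p2.5, p97.5)"` rounded to two decimals (rounding happens only
#' here, at serialisation; `-0.00` is preserved). All-missing cells print
#' `"NA"`.
#'
#' @param summary a [summarize_records()] result.
#' @param candidates column order; defaults to order of appearance.
#' @return a data frame with a `measure` column and one character column
#'   per candidate.
#' @export
format_summary_table <- function(summary,
                                 candidates = unique(summary$candidate)) {
  fmt <- function(m, lo, hi) {
    ifelse(is.na(m), "NA",
           sprintf("%.2f (%.2f, %.2f)", m, lo, hi))
  }
  out <- data.frame(measure = MEASURE_NAMES, stringsAsFactors = FALSE)
  for (cand in candidates) {
    sub <- summary[summary$candidate == cand, ]
    sub <- sub[match(MEASURE_NAMES, sub$measure), ]
    out[[cand]] <- fmt(sub$mean, sub$p2.5, sub$p97.5)
  }
  out
}

#' Boxplot of per-replicate differences for one measure
#'
#' One box per candidate, in catalog order, with a zero reference line —
#' the canonical visualisation of how far each proxy model sits from the
#' true model on a given measure.
#'
#' @param records difference records from [run_scenario()].
#' @param measure one of [MEASURE_NAMES].
#' @param path output image path (extension selects the device, e.g.
#'   `.png` or `.svg`); `NULL` to skip writing.
#' @return invisibly, the ggplot object (its `data` holds exactly the
#'   plotted difference records).
#' @export
boxplot_export <- function(records, measure, path = NULL) {
  if (!measure %in% MEASURE_NAMES) {
    stop("unknown measure '", measure, "'; valid measures are: ",
         paste(MEASURE_NAMES, collapse = ", "))
  }
  dat <- records[records$measure == measure & !is.na(records$diff), ]
  dat$candidate <- factor(dat$candidate, levels = unique(records$candidate))
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$candidate,
                                          y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "type of model",
                  y = paste("difference in", measure, "to the true model")) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(path)) {
    ggplot2::ggsave(path, gg, width = 8, height = 4.5, dpi = 150)
  }
  invisible(gg)
}

#' Run a full simulation experiment
#'
#' Builds the scenario grid, optionally subsamples it, runs every scenario,
#' and writes a report bundle: the long-format difference records, the
#' mean (95% range) summary table, boxplots, and a provenance file from
#' which the run can be reproduced exactly.
#'
#' @param config grid configuration (see [build_grid()]).
#' @param out_dir output directory; created if needed. `NULL` skips all
#'   file output.
#' @param scenario_fraction fraction of grid scenarios to run, sampled
#'   deterministically from the master seed.
#' @param reps optional override of replicates per scenario.
#' @param catalog optional candidate catalog.
#' @param boxplot_measures measures to render as boxplots.
#' @param format `"csv"` or `"tsv"` for the delimited outputs.
#' @return invisibly, a list with `records`, `summary`, `table`,
#'   `failures` and `provenance`.
#' @export
run_experiment <- function(config, out_dir = NULL, scenario_fraction = 1,
                           reps = NULL, catalog = NULL,
                           boxplot_measures = "AUC",
                           format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  grid <- build_grid(config)
  if (scenario_fraction < 1) {
    set.seed(derive_seed(config$seed, 999983L))
    keep <- sort(sample.int(length(grid),
                            max(1L, round(scenario_fraction * length(grid)))))
    grid <- grid[keep]
  }
  if (!is.null(reps)) {
    grid <- lapply(grid, function(s) { s$n_reps <- as.integer(reps); s })
  }
  failures <- character()
  records <- do.call(rbind, lapply(grid, function(spec) {
    tryCatch(run_scenario(spec, catalog = catalog),
             error = function(e) {
               failures <<- c(failures,
                              paste0(spec$scenario_id, ": ",
                                     conditionMessage(e)))
               NULL
             })
  }))
  summary <- summarize_records(records)
  table <- format_summary_table(summary)
  provenance <- list(
    package = "truemodelsim",
    version = as.character(utils::packageVersion("truemodelsim")),
    r_version = R.version.string,
    master_seed = config$seed,
    n_scenarios_grid = length(build_grid(config)),
    n_scenarios_run = length(grid),
    scenario_fraction = scenario_fraction,
    reps_override = if (is.null(reps)) NA else reps,
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- paste0(".", format)
    utils::write.table(records, file.path(out_dir, paste0("records", ext)),
                       sep = sep, row.names = FALSE, quote = FALSE)
    utils::write.table(table, file.path(out_dir, paste0("summary", ext)),
                       sep = sep, row.names = FALSE, quote = TRUE)
    for (m in boxplot_measures) {
      boxplot_export(records, m,
                     file.path(out_dir, paste0("boxplot_", m, ".png")))
    }
    jsonlite::write_json(provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (length(failures)) {
      writeLines(failures, file.path(out_dir, "error_manifest.txt"))
    }
  }
  invisible(list(records = records, summary = summary, table = table,
                 failures = failures, provenance = provenance))
}
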
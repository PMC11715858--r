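# truemodelsim

Can conventional model performance measures identify the model that
actually generated the outcome?

Clinical risk prediction models (for cardiovascular disease risk, say) are
routinely selected by comparing discrimination and calibration on held-out
data. `truemodelsim` asks a sharper question by Monte-Carlo simulation:
when a binary outcome is *known* to come from a logistic model

    y_i ~ Bernoulli( expit(beta0 + beta1 * x_i1 [+ beta2 * x_i2]) ),

do 25 conventional measures — C statistic, Somers' Dxy, g-index,
Harrell's U/D/Q, calibration-in-the-large odds ratio, Emax/Eavg/ECI
calibration errors, Brier score, nine pseudo-R² variants, the global
shrinkage factor gamma = (chi²_LR − df)/chi²_LR, and the IDI — separate
that true model from proxy candidates? The candidates mimic real
modelling practice: extra noise variables (independent or correlated with
the causal predictor at rho = 0.3/0.5/0.8), stepwise-AIC selection with
the causal variable included or excluded, heuristic shrinkage, dropped or
replaced causal predictors, and a flip-coin reference that predicts risk
0.5 for everyone.

The package provides:

* `build_grid()` / `make_dataset()` — a scenario-grid simulator
  (effect sizes log(1)…log(4), continuous/binary predictors, correlated
  proxies via a latent-Gaussian construction, deterministic per-scenario
  RNG substreams, 80/20 train/test splits);
* `univariate_catalog()` (10 candidates) / `multivariate_catalog()` (12)
  and `build_candidates()` — logistic fits, `stepAIC` selection,
  shrinkage, flip-coin;
* `measure_panel()` and the individual measure functions — the
  25-measure panel computed on the test set;
* `run_scenario()` / `run_experiment()` / `summarize_records()` /
  `boxplot_export()` — per-replicate candidate-minus-true differences
  pooled into `mean (2.5th, 97.5th percentile)` report tables and
  boxplots, with provenance for exact reruns.

## Worked example

Five replicates of one univariate scenario (continuous predictor,
beta1 = log 2, baseline risk 0.2, n = 15,000 per replicate, 80/20 split):

```r
library(truemodelsim)
spec <- scenario_spec("demo", "univariate", "continuous",
                      beta0 = qlogis(0.2), betas = log(2),
                      n_total = 15000L, n_reps = 5L, seed = 42L)
records <- run_scenario(spec)
tab <- format_summary_table(summarize_records(records))
tab[tab$measure %in% c("AUC", "OR_caliLarge", "brierScore",
                       "GlobalShrinkageFactor"),
    c("measure", "TrueModel", "FlipCoin", "AddIndModel", "AICAddModel")]
```

```
               measure         TrueModel             FlipCoin          AddIndModel          AICAddModel
                   AUC 0.69 (0.68, 0.69) -0.19 (-0.19, -0.18)   0.00 (-0.00, 0.00) -0.04 (-0.05, -0.03)
          OR_caliLarge 0.98 (0.94, 1.01)    2.47 (2.42, 2.53) -0.00 (-0.00, -0.00)   0.00 (-0.01, 0.01)
            brierScore 0.16 (0.16, 0.16)    0.09 (0.09, 0.09)  -0.00 (-0.00, 0.00)    0.00 (0.00, 0.01)
 GlobalShrinkageFactor 1.00 (1.00, 1.00)                   NA -0.00 (-0.00, -0.00) -0.00 (-0.00, -0.00)
```

The `TrueModel` column shows the measure itself; every other column shows
the difference to the true model (candidate minus true). Reading it: the
flip-coin model is separated decisively on every measure (C statistic 0.19
lower, Brier 0.09 worse, grossly miscalibrated); adding a pure noise
variable to the true model changes nothing to two decimals — conventional
measures do not penalise non-causal predictors; and even the stepwise
model that is *forbidden* to use the causal variable (`AICAddModel`) loses
only 0.04 of C statistic here because the correlated proxies carry most of
the signal. The shrinkage factor of 1.00 says a single-predictor model at
n = 12,000 training rows is essentially not overfitted.

`run_experiment(default_univariate_config(), out_dir = "results")` scales
this to the full 112-scenario grid and writes record files, summary
tables, boxplots and a provenance file; a thin command-line wrapper lives
in `inst/scripts/run_experiment.R`.

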
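---
title: "Can performance measures identify the outcome-generating model?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Can performance measures identify the outcome-generating model?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truemodelsim)
```

## The question

Clinical risk prediction models are usually chosen by comparing
discrimination and calibration measures on held-out data and adopting the
"best performing" candidate. If the data really were generated by some
logistic model — a fixed formula linking causal predictors to the binary
outcome — would those measures single that model out? `truemodelsim`
answers this by direct simulation: outcomes are generated from a known
("true") logistic model, a catalog of plausible proxy candidates is trained
on each simulated training set, and the per-replicate difference of every
conventional performance measure between each candidate and the true model
is summarised across a grid of scenarios. A measure that cannot separate a
proxy from the true model at the scale of its own sampling noise cannot be
used to identify the true model in practice.

## The generating model and its scenario grid

One replicate of a scenario draws `n_total` subjects. Causal predictors are
standard Gaussian (continuous) or Bernoulli with prevalence `p` (binary);
the outcome is

$$y_i \sim \mathrm{Bernoulli}\bigl(\operatorname{expit}(\beta_0 + \beta_1 x_{i1}
  [+ \beta_2 x_{i2} + \beta_{12} x_{i1} x_{i2}])\bigr).$$

A scenario fixes $(\beta_0, \beta_k,$ predictor kinds, prevalence,
correlations, $n)$; a grid is the Cartesian product of factor levels
(`build_grid()`), with one RNG substream per scenario derived from a master
seed by counter-based mixing, so scenarios and replicates can run in any
order and still reproduce bitwise.

Default levels, all overridable through the configuration:

* **Univariate** (single causal predictor, `n_total` 15,000):
  $\beta_1 \in \{\log 1, \log 1.3, \log 1.7, \log 2, \log 2.5, \log 3,
  \log 4\}$, $\beta_0 \in \operatorname{logit}\{0.1, 0.2, 0.3, 0.5\}$,
  predictor continuous or binary, prevalence $\{0.3, 0.5\}$ — 112
  scenarios. The null level $\log 1$ is kept: near-chance scenarios are
  part of the design (they produce the negative tail of the shrinkage
  factor and C statistics at 0.5).
* **Multivariate** (two causal predictors, `n_total` 3,000): both effects
  in $\{\log 1.3, \ldots, \log 4\}$ — the null level is excluded because a
  "causal" predictor with no effect contradicts the two-predictor design
  and a null-null cell makes the likelihood-ratio $\chi^2$ of the true
  model collapse, sending the shrinkage factor to arbitrarily large
  negative values; the published summaries (shrinkage 95% range bounded at
  0.91, C bounded well above 0.5) are only consistent with informative
  effects. Kinds are continuous+continuous or continuous+binary, causal
  correlation $\{0, 0.3, 0.5\}$, intercepts and prevalences as above —
  1,728 scenarios.

The train/test split is a uniform random permutation with
`floor(n_total * 0.8)` training rows. A split that leaves either part
without both outcome classes is regenerated from the next substream (at
most 100 attempts); at the default sizes this is essentially never needed,
but it protects extreme-intercept configurations.

### Proxy predictors

Each dataset also carries non-causal columns that candidate models can
(mis)use: one independent proxy per causal kind and one correlated proxy
per configured $\rho \in \{0.3, 0.5, 0.8\}$ and causal target. A
continuous proxy of a continuous target is
$\rho z + \sqrt{1-\rho^2}\,\varepsilon$ on the standardised target. Any
pairing that involves a binary variable goes through a latent Gaussian: the
binary variable's latent normal is reconstructed by truncated-normal
sampling given its observed value, and the latent correlation is solved by
bisection so that the *observed-scale* Pearson correlation equals $\rho$
(point-biserial identity for mixed pairs, bivariate-normal quadrant
probability for binary pairs). Requested correlations that are unattainable
for the margins (e.g. high $\rho$ with an extreme prevalence) raise an
error rather than silently under-delivering.

## The candidate catalog

Ten univariate candidates: the true model; the flip-coin reference
(constant risk 0.5 — the only constant consistent with a Brier score of
exactly 0.25 and a C statistic of 0.5 for every outcome vector); the true
model plus one independent (`AddIndModel`) or one $\rho$-correlated proxy
(`Add03Model`, `Add05Model`, `Add08Model`); bidirectional stepwise-AIC
selection over causal-plus-proxies starting from the full model with the
causal variable included (`AICTrueModel`) or excluded (`AICAddModel`);
and heuristically shrunken versions of the true fit (`ShrinkTrueModel`)
and of the full proxy fit with the causal variable excluded
(`ShrinkAddModel`).

Twelve multivariate candidates: true model, flip-coin, the single-predictor
submodels `Variable1`/`Variable2`, the true model plus one extra variable
(independent continuous, correlated continuous, categorical), and a
missing-variable-1 group in which $x_1$ is dropped and replaced by an
independent proxy, a proxy correlated with $x_1$, a proxy correlated with
$x_2$, or combinations (`AddIndCorrVar1`, `AddCorrVar1AddCorrVar2`). The
group's exact published definitions are not available; this reconstruction
follows the table's header groups and is configurable through
`candidate_spec()` if a different catalog is wanted.

Stepwise selection is `MASS::stepAIC` in both directions from the full
start model with `AIC = -2\ell + 2(k+1)`; variables are sorted by name so
ties break deterministically, and the search may legitimately reduce
`AICTrueModel` to the true model itself (those self-comparisons are
retained in the summaries). Separated fits are capped at $|\hat\beta| \le
15$ and flagged rather than allowed to crash a grid run.

## The 25-measure panel

All measures are computed on the held-out test set from the candidate's
predicted risks $\hat p$ (clipped to $[10^{-10}, 1-10^{-10}]$), except the
global shrinkage factor, which is a training quantity by definition.
Dialect choices that the literature leaves open are fixed as follows:

* **U, D, Q** use the validation-likelihood convention: with the logistic
  recalibration $\operatorname{logit} P(y{=}1) = a + b \operatorname{logit}
  \hat p$, $D = (\chi^2_{\mathrm{free\ vs\ null}} - 1)/n$ and $U =
  (\chi^2_{\mathrm{free\ vs\ identity}} - 2)/n$ (one parameter fewer is
  subtracted when constant predictions make the slope inestimable);
  $Q = D - U$ exactly.
* **Calibration-in-the-large OR** is predicted odds over observed odds,
  $\operatorname{odds}(\overline{\hat p}) / \operatorname{odds}(\bar y)$.
* **Emax/E-mean** come in two families from the recalibration curve
  $c(q) = \operatorname{expit}(\hat a + \hat b \operatorname{logit} q)$:
  `_ab` evaluates $|q - c(q)|$ over the observed predictions (whose range
  is $[\min \hat p, \max \hat p]$), `_01` over a fixed grid
  $0.001, 0.002, \ldots, 0.999$ (the grid itself is a package choice).
  For constant predictions the means are reported missing and the maxima
  collapse to $|\hat p - \bar y|$.
* **Eavg/ECI** use `stats::lowess` with span 2/3 and zero robustness
  iterations — the conventional calibration-curve default — and ECI is
  scaled by 100 (mean *squared* error on the percentage-point scale).
* **Pseudo-$R^2$** values are computed from the test-set predictions
  directly, so a badly calibrated candidate can go negative (visible in
  the flip-coin column of Efron's $R^2$). An alternative dialect refits
  the candidate's formula on the test set, which forces the flip-coin
  likelihood-based $R^2$ to zero; the prediction-based dialect is adopted
  because validation predictions, not refits, are what a model deployed in
  practice produces. `R2_McFaddenAdj` counts `k` as the candidate's
  non-intercept terms (0 for flip-coin).
* **Global shrinkage factor** $\gamma = (\chi^2_{LR} - k)/\chi^2_{LR}$
  from the training fit; missing for flip-coin and for $\chi^2_{LR} = 0$.
  `Shrink*` candidates multiply slopes by $\gamma$ and re-estimate the
  intercept with the shrunken linear predictor as an offset.
* **IDI_diff1** is the discrimination-slope difference against the null
  model, which is analytically identical to Tjur's $R^2$; both are kept
  because reports list both rows.

Missing values propagate per measure, never as panel failure, mirroring the
`NA` cells of the report tables.

## Reporting

`run_scenario()` differences every candidate's panel against the same
replicate's true-model panel (candidate minus true); `summarize_records()`
pools all scenario-by-replicate values per cell — replicates are pooled
raw, which equals scenario-weighted pooling here because every scenario
contributes the same number of replicates — and reports the mean with the
empirical 2.5th/97.5th percentiles (type-7 linear interpolation). Rounding
to two decimals happens only at serialisation, where `-0.00` is preserved
deliberately: a mean that is negative but rounds to zero is itself a
finding. `boxplot_export()` draws one box per candidate against a zero
reference line.

## A small demonstration

```{r demo, eval = FALSE}
spec <- scenario_spec("demo", "univariate", "continuous",
                      beta0 = qlogis(0.2), betas = log(2),
                      n_total = 15000L, n_reps = 5L, seed = 42L)
records <- run_scenario(spec)
format_summary_table(summarize_records(records))
```

Across replicates the flip-coin column separates cleanly on every measure,
while the noise-augmented candidates sit at `0.00 (-0.00, 0.00)` — the
central phenomenon this package exists to exhibit: conventional measures
do not penalise a model for carrying non-causal predictors.

## Problem sizes and runtime

Full grids with 100 replicates per scenario (the study scale) are hours of
compute; the package therefore treats subsampling as first-class.
`run_experiment()` takes a `scenario_fraction` and a replicate override,
records both in its provenance file, and its acceptance-scale defaults —
50 scenarios per grid, 10 replicates, full per-replicate sample sizes
(univariate 15,000, multivariate 3,000) — reproduce the stable aggregate
quantities (mean calibration OR, mean U, mean shrinkage factor, mean
noise-candidate differences) in minutes on one core. Quantities that
average over the *whole* grid, such as the grid-mean C statistic, depend on
the exact factor levels, and the reconstructed default grid is not
guaranteed to match an unpublished original on those.

## What the simulations do and do not show

The generator emulates the statistical skeleton of cohort data — mixed
predictor kinds, realistic baseline risks, correlated measurement proxies —
but deliberately omits missing data, survey weights, measurement error in
the outcome, non-linear or time-varying effects, and unmeasured
confounding. Passing tests therefore show that the measures cannot
distinguish true from proxy models *even in this idealised setting*; they
do not show that any particular real dataset was generated by a logistic
model. The optional interaction term (`interaction_beta`) is the only
departure from linearity supported; survival outcomes and penalised or
machine-learning candidates are out of scope.
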
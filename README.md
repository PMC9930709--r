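# mtnnps

Propensity-score analysis when covariates have missing values, built around
a **multi-task neural network** that estimates propensity scores and fills
missing covariates in one jointly trained model.

## Who this is for

Biostatisticians and epidemiologists estimating treatment effects from
observational data by inverse probability weighting (IPW) when one or more
confounders are incompletely observed — and anyone benchmarking
missing-data strategies for propensity models (missing-indicator,
multiple imputation, complete-case) under controlled MCAR/MAR/MNAR
missingness.

## The model

The propensity score `e(X) = Pr(T = 1 | X)` balances confounders between
treatment groups; IPW weights treated subjects by `1/e` and controls by
`1/(1 - e)`, and the treatment effect is the treatment coefficient of a
weighted regression of the outcome. With missing covariate cells the score
cannot be fit directly. The package's core estimator is a neural network
with a shared hidden trunk and three output heads trained simultaneously:

* reconstruction of the covariates (squared error on observed continuous
  cells, cross-entropy on observed binary cells),
* the propensity score (sigmoid unit, cross-entropy against treatment),
* the missingness pattern (one sigmoid unit per covariate, cross-entropy
  against the mask),

minimizing `w1·L_rec + w2·L_prop + w3·L_mask`. Inputs are the standardized,
zero-filled covariates concatenated with the missingness mask; training
uses denoising corruption of observed cells so the reconstruction head
learns to impute rather than copy (see the methods vignette,
`vignettes/mtnn-propensity-methods.Rmd`).

Also included: the classical comparators (missing-indicator logistic
regression, MICE with Bayesian linear regression, complete-case), a
calibrated MCAR/MAR/MNAR missingness simulator, standardized mean
difference (SMD) balance diagnostics, a Monte Carlo harness producing
mean/SD/RMSE tables over scenario × mechanism × rate × method grids, and a
real-world (LaLonde-layout) pipeline with a synthetic offline stand-in
table.

## Worked example

```r
library(mtnnps)
set.seed(1)
d      <- simulate_scenario(scenario_spec(n_subjects = 1000, true_effect = 1))
masked <- impose_missingness(d, missingness_spec("MAR", 0.5))
masked
#> <observed_dataset> n = 1000 | K = 2 | treated = 327 | missing cells = 475 (23.8%)

model <- mtnn_train(masked, mtnn_config())
model
#> <mtnn_model> trunk 8-8 | K = 2 | epochs trained = 134 | converged = TRUE

ps  <- predict_propensity(model, masked)
w   <- ipw_weights(ps, masked$treatment)
imp <- mtnn_impute(model, masked)
weighted_effect(masked$outcome, masked$treatment, imp, w)
#> <effect_estimate> ipw ( with_covariates ) beta_hat = 1.18388

smd_report(imp, masked$treatment, w)
#>   covariate smd_unweighted smd_weighted
#> 1        X1      0.6368551   0.06277577
#> 2        X2      0.5869722   0.07401110
```

The true effect is 1; a single dataset at 50% MAR missingness estimates
1.184 (the Monte Carlo mean over many repetitions sits much closer — see
`reproduce_table()`), and weighting shrinks the covariate imbalance from
SMD ≈ 0.6 to below 0.08. The comparators on the same masked data:

```r
fit <- missing_indicator_ps(masked)
weighted_effect(masked$outcome, masked$treatment, fit$design,
                ipw_weights(fit$propensity, masked$treatment))$beta_hat
#> [1] 1.19126

imps <- mice_impute(masked)
mi_pooled_effect(imps, masked$treatment, masked$outcome,
                 ipw_effect_estimator())
#> [1] 1.211285
```

Grid-scale evaluation (this is the Monte Carlo machinery behind the
package's summary tables; expensive at full scale):

```r
grid <- experiment_grid(mechanisms = "MCAR", repetitions = 200)
tab  <- reproduce_table(grid, csv_path = "table1.csv")
```

A command-line front end with `simulate`, `run-cell`, `reproduce-table1`,
`balance-report` and `real-world` subcommands is installed at
`inst/cli/mtnnps`.

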
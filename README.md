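# dfpi: propensity score analysis with confounders missing not at random

Observational treatment-effect estimation by inverse-probability-of-
treatment weighting (IPTW) breaks down when confounders are missing — and
especially when they are **missing not at random** (MNAR), i.e. when the
probability that a value is missing depends on the unobserved value itself
or on an unobserved auxiliary. The missingness pattern — the vector of
per-covariate missing indicators `S` — then carries information that the
propensity model must use.

`dfpi` implements, behind one fitting function, the family of
missingness-pattern-aware estimators for this setting:

| method | imputation | propensity model | indicators in PS model | pooling |
|---|---|---|---|---|
| `mp_lr`, `mp_rf` | none (per-group mean fill) | logistic / forest per pooled pattern group | no | Rubin's rules not needed |
| `mimp_lr`, `mimp_rf` | chained-equations PMM (m = 10) | logistic / forest | yes | Rubin's rules |
| `pi_i`, `pi_u` | supervised / unsupervised forest proximity | logistic | yes | — |
| `dfpi` | **dual-forest proximity** | logistic | yes | — |

The package's namesake, **dual-forest proximity imputation (DFPI)**,
iterates: augment the current completion with the indicators,
`X* = [X | S]`; fit a treatment-classification forest and an
outcome-regression forest on `X*`; average their co-leaf proximity
matrices, `M_CS = (M_T + M_Y) / 2` (zero diagonal); and refresh every
missing cell by proximity-weighted donation — continuous cells as the
weighted mean of donors' current values, binary cells by
marginal-proportion-weighted vote. Proximities from the treatment forest
encode similarity in selection, those from the outcome forest similarity in
prognosis; their average targets exactly what makes a covariate a
confounder.

Around the imputers, the package provides pattern extraction and
Qu–Lipkovich-style pooling to a minimum stratum size of 100, logistic and
out-of-bag forest propensity scores, ATE/ATT weights, the Hájek weighted
effect with Taylor-linearized SE, Rubin's-rule pooling, weighted balance
diagnostics (0.05 standardized-difference criterion), a weighted Poisson
effect model for non-negative outcomes, a calibrated Monte Carlo generator
covering MAR and five MNAR mechanisms, and a simulation-study driver with
relative-bias / MSE / factorial-effect-size summaries.

## Worked example

```r
library(dfpi)

# a synthetic observational study: n = 500, 10 confounders (5 continuous,
# 5 binary), 20% treated, focused-direct MNAR missingness at 30%
cfg <- sim_config(n = 500, p = 10, missing_rate = 0.3, mechanism = "FD_MNAR")
d <- simulate_mnar_dataset(cfg, seed = 1)

fit <- mpa(d$X_observed, d$Z, d$Y, method = "dfpi",
           control = impute_control(n_trees = 100, seed = 1))
print(fit)
#> Missingness-pattern PSA fit: method DFPI, estimand ATE
#>   ATE = 0.4830 (SE 0.1691)
confint(fit)
#>         2.5 %    97.5 %
#> ATE 0.1515784 0.8143681
```

The generator's true effect is 0.5; the DFPI chain recovers 0.483 with a
linearized SE of 0.169, so the 95% interval covers the truth. `summary(fit)`
adds the overlap and balance diagnostics:

```r
summary(fit)
#> z = 2.856, p = 0.0043
#> Common support (propensity quantiles):
#>           min   q25 median   q75   max
#> treated 0.035 0.157  0.250 0.420 0.861
#> control 0.009 0.058  0.119 0.193 0.756
#> Covariate balance: mean |d| = 0.077, max = 0.229, 6 of 10 >= 0.05
```

Both arms span overlapping propensity ranges (common support holds);
at this sample size some covariates remain above the 0.05 balance
threshold, which is typical for a single n = 500 draw at 30% MNAR
missingness. `plot(fit)` draws the overlap histograms;
`mpa(..., method = "mimp_lr")` runs the multiple-imputation competitor and
pools by Rubin's rules; `coef()`, `vcov()`, `weights()` behave as usual.

A thin command-line front end is installed under `inst/cli/mnarps.R`
(`simulate`, `impute`, `estimate`, `study` subcommands) for scripted use.

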
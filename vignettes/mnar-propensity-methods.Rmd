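---
title: "Propensity score analysis with MNAR confounders: dual-forest proximity imputation and its competitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity score analysis with MNAR confounders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfpi)
```

## The problem

Inverse-probability-of-treatment weighting (IPTW) estimates a causal
treatment effect from observational data by weighting each unit with the
inverse of its propensity score $e(X) = P(Z = 1 \mid X)$. When confounders
are missing — and especially when they are *missing not at random* (MNAR),
i.e. the probability that a cell is missing depends on the unobserved value
itself or on an unobserved auxiliary variable — the propensity model cannot
simply be fit to complete cases. The missingness pattern (the binary vector
$S_i$ of per-covariate missing indicators, coded here as $S = 1$ for a
missing cell) then carries information about the unobserved values, and
methods that condition on it can reduce bias where ordinary multiple
imputation cannot.

This package implements a family of such estimators behind one fitting
function, `mpa()`:

* **MP-LR / MP-RF** — stratify on pooled missingness patterns and fit a
  separate logistic-regression or random-forest propensity model per pooled
  group;
* **MIMP-LR / MIMP-RF** — multiple imputation by chained equations with
  predictive mean matching, then a propensity model that includes the
  missing indicators as covariates, pooled by Rubin's rules;
* **PI-I / PI-U** — iterative random-forest proximity imputation before a
  standard propensity fit, using a supervised forest for the outcome
  (PI-I) or an unsupervised, synthetic-class forest on the covariates and
  indicators only (PI-U);
* **DFPI** — dual-forest proximity imputation, the package's namesake.

## Dual-forest proximity imputation

DFPI iterates four steps, starting from a strawman completion (column
medians for continuous cells, observed modes for binary cells):

1. augment the current complete matrix with the missing indicators,
   $X^{*(m)} = [X^{(m)} \mid S]$;
2. fit two random forests on $X^{*(m)}$: a classification forest predicting
   the treatment and a regression forest predicting the outcome, and record
   for every observation its terminal node in every tree;
3. form each forest's proximity matrix — the proportion of trees in which a
   pair of observations shares a terminal node — and average the two
   element-wise into the *confounder-signified* proximity matrix
   $M_{CS} = \tfrac12 (M_T + M_Y)$, with zeroed diagonal so no observation
   donates to itself;
4. refresh every originally missing cell by a proximity-weighted donor
   rule: continuous cells become the $M_{CS}$-weighted mean of all donors'
   current values (weights normalized per row); binary cells receive the
   category maximizing (observed marginal proportion) × (proximity-weighted
   support), with ties going to the lower category.

The dual-forest construction is the point: the treatment forest makes
donors similar with respect to the selection process, the outcome forest
with respect to prognosis, so that proximities encode both sides of what
defines a confounder, and the missing indicators inside $X^*$ let the
forests exploit informative missingness itself.

### Convergence behaviour

Iteration stops when the summed absolute change over originally missing
continuous cells, relative to their summed magnitude, falls below `tol`
(default $10^{-5}$) *and* no binary cell changed — or at `max_iter`
(default 10). In practice the relative change plateaus after three to five
sweeps at the level of forest-resampling jitter (roughly $10^{-1}$ on the
relative scale) rather than shrinking to the tolerance: each sweep refits
both forests, and even with frozen seeds the trees restructure as the
imputed cells move, so the map being iterated is stochastic. The tolerance
therefore acts as an early exit for near-degenerate problems (e.g. no
missing cells), while `max_iter` is the effective stopping rule; the
per-sweep trace is returned (`$trace`) so users can see the plateau. Runs
that end at the cap carry a warning and `converged = FALSE`, which is the
expected state, not a failure.

## The propensity and estimation stage

After completion (or per pooled pattern group), propensity scores come from
maximum-likelihood logistic regression or from a probability forest, in
which case the score is the *out-of-bag* treated-class proportion and is
clipped to $[0.005, 0.995]$ — in-bag forest probabilities memorize the
training labels and collapse to 0/1. Logistic scores are deliberately left
unclipped and un-penalized even under quasi-separation: the instability of
pattern-stratified logistic fits on small strata is a property of those
methods under study, and smoothing it away would change the estimator being
evaluated. Only an outright IRLS failure triggers a ridge rescue (with a
warning).

ATE weights are $Z/e + (1-Z)/(1-e)$; ATT weights are
$Z + (1-Z)\,e/(1-e)$. The effect is the Hájek (weight-normalized)
difference of weighted outcome means; its standard error comes from Taylor
linearization under the with-replacement approximation, without a
finite-population correction and without propagating propensity-estimation
uncertainty — the usual survey-weighted practice, and numerically identical
to the HC0 sandwich of the weighted least-squares fit of $Y$ on $Z$. For
multiply imputed data, per-imputation estimates and variances are pooled by
Rubin's rules, $T = W + (1 + 1/m)B$. Balance diagnostics report absolute
weighted standardized mean differences against the 0.05
baseline-equivalence threshold, averaging means and standard deviations
across imputations before forming the ratio.

## Pattern pooling

Propensity models per missingness pattern need enough observations per
stratum; the pooling rule enforces a minimum of 100 (configurable).
Patterns already at the minimum stand alone. For the remainder,
`pool_patterns()` offers two readings of the accumulate-to-100 rule:

* **chain** (default): the largest small pattern opens a cell and absorbs
  the nearest unassigned small patterns (Euclidean distance between
  indicator vectors; ties to the larger count, then lexicographic order)
  until the cell reaches the minimum; a final short cell joins the closest
  existing group. At low missingness this yields several moderate strata —
  matching the small-stratum instability (extreme propensity scores,
  occasional non-convergence) that motivates the pooling rule in the first
  place.
* **seed**: every small pattern merges directly into the closest
  large-pattern group; with no large pattern at all, a single group.

The chain variant is the default because only it produces the multi-stratum
regime at 10–30% missingness; the seed variant collapses nearly everything
into one stratum there, making MP-LR indistinguishable from plain
mean-filled logistic PSA. Within each pooled group the propensity model
uses all covariates after mean-filling missing cells from the overall
observed column means (`mp_restrict = "mean_fill"`); restricting each group
to its fully observed columns is available (`"observed_columns"`) and
produces markedly more variable estimates, since omitted confounders then
differ by stratum.

## The synthetic data generator

`sim_config()` + `calibrate_coefficients()` + `generate_dataset()` +
`impose_missingness()` emulate a canonical observational study:

* $p$ confounders from a multivariate standard normal (default
  exchangeable correlation $\rho = 0.2$; identity and user matrices
  supported), with columns $\lceil p/2\rceil + 1, \dots, p$ dichotomized at
  0 into balanced binaries. The exchangeable default stands in for an
  empirical correlation matrix estimated from survey data that is not
  publicly available; it is the one deliberate divergence of this generator
  from the study design it emulates.
* treatment from a logistic model whose slopes are drawn from
  $U(-0.4, 0.4)$ and rescaled by a single constant so the McKelvey–Zavoina
  pseudo-$R^2$, $\operatorname{var}(X\beta) / (\operatorname{var}(X\beta) +
  \pi^2/3)$, hits its target (default 0.2), with the intercept root-found
  for a 0.2 treated fraction. A deterministic threshold variant
  (`deterministic_threshold = TRUE`) replaces the Bernoulli draw by
  $Z = 1\{\beta_0 + X\beta > 0\}$; the default keeps the latent
  logistic(0,1) error because a hard threshold destroys overlap and with it
  the positivity assumption IPTW needs.
* a linear outcome $Y = X\pi + \delta Z + e$, $e \sim N(0,1)$, with
  $\delta = 0.5$ and slopes from $U(0.1, 0.8)$ rescaled (closed form, from
  the sample moments of $X\pi$ and $\delta Z$) so the population $R^2$ is
  0.2;
* missingness in columns $2..p$ (column 1 always observed) from one of six
  mechanisms — MAR (driven by $X_1$), focused-direct (the target value
  itself), focused-indirect (an unobserved $N(0,1)$ auxiliary, drawn one
  per target column), diffuse (all confounders), and two interaction forms
  — each with slopes from $U(0.1, 0.5)$, a latent logistic(0,1) error, and
  the intercept root-found so the marginal per-column missing rate hits its
  target (10/30/50% in the study design).

Calibration uses a fixed-seed Monte Carlo sample of $10^5$ draws, so
calibration is deterministic given the configuration and achieved values
(stored in `$achieved`) are within ±0.01 of their targets. Under
exchangeable or identity correlation, the missingness intercept is solved
once per column type (continuous/binary targets have identical joint laws),
which is exact and roughly ten times cheaper than per-column root-finding;
user-supplied correlation matrices fall back to per-column roots.
Population coefficients are redrawn in every replication of a simulation
condition (the alternative is `fix_coefficients = TRUE`): redrawing makes
the Monte Carlo average marginal over coefficient configurations rather
than conditional on one draw, at the cost of folding coefficient
variability into the empirical SD of the estimates.

What the generator does *not* emulate: skewed or heavy-tailed covariates,
survey weights, measurement error, treatment-effect heterogeneity, or
missingness in treatment and outcome. Tests passing on these synthetic
conditions show the estimators behave as designed under the stated model;
they do not certify performance on real data violating it.

## Numerical and design choices

* Proximities are accumulated per terminal node via a compiled kernel whose
  cost is the sum of squared leaf sizes per tree, not $n^2 B$; it is tested
  for exact equality against the naive per-pair count, and the dual-forest
  average is fused into a single pass.
* Forests default to 500 trees and `mtry` $= \lfloor\sqrt{q}\rfloor$ over
  the $q$ available features, single-threaded for reproducibility; node
  size keeps the engine defaults. Proximities use all training rows
  (in-bag included); an out-of-bag-pairs variant exists but is off by
  default.
* The unsupervised forest uses the synthetic-class construction: each
  column independently permuted to form a shadow sample, a classification
  forest separating real from shadow rows, proximities read off the real
  rows.
* MICE uses predictive mean matching with 5 donors and Bayesian
  coefficient draws in every univariate model, conditioning on all other
  confounders, the treatment and the outcome; 10 chains by default,
  5 sweeps each. PMM keeps binary columns binary without a separate model
  family. A near-singular design falls back to a small ridge, logged.
* All-zero proximity rows (no donor shares a leaf) fall back to uniform
  weights over the column's observed donors and are recorded on the result.
* Degenerate inputs error early and namedly: constant treatment, fully
  missing columns, non-binary declared-binary cells, missing treatment or
  outcome values.

## Factorial effect sizes

`anova_effect_sizes()` decomposes cell-level simulation summaries (e.g.
relative bias per design cell) by a fixed-effects factorial ANOVA and
reports, per modeled effect, the generalized eta-squared
$SS_{\text{effect}} / SS_{\text{total}}$ and the proportion of effect
variance $SS_{\text{effect}} / \sum_k SS_{\text{effect}(k)}$. Working on
cell means approximates the replication-level mixed design: PEV over the
modeled effects is reproduced, but the residual entering $\eta^2_G$ is the
unmodeled cell variation, not the within-cell Monte Carlo error, so
$\eta^2_G$ is labeled approximate.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run scaled-down versions of the
full study (which crosses 504 conditions with 1,000 replications each):
calibration checks on $10^5$-draw samples, effect-recovery on 60–200
replications at $n = 2000$, and table-cell reproductions at 50
replications per sub-condition with 100 trees. For the DFPI cells, the
proximity iteration is capped at 6 sweeps, past the plateau of its
relative-change trace observed in every pilot, so the cap changes compute,
not the estimand. These sizes were chosen as the smallest runs whose Monte
Carlo error is comfortably below the differences the checks assert.

## A worked example

```{r example, eval = FALSE}
library(dfpi)

cfg <- sim_config(n = 500, p = 10, missing_rate = 0.3,
                  mechanism = "FD_MNAR")
d <- simulate_mnar_dataset(cfg, seed = 1)

fit <- mpa(d$X_observed, d$Z, d$Y, method = "dfpi",
           control = impute_control(n_trees = 100, seed = 1))
print(fit)
summary(fit)
confint(fit)
plot(fit)       # propensity overlap by arm
```

## Known limitations

* The exact correlation structure, per-group design matrix of the
  pattern-stratified logistic fits, and the unsupervised-forest
  construction of the study this package emulates are not fully published;
  the alternatives implemented here are documented above and selectable,
  but cell-level agreement with the original tables is approximate by
  construction.
* DFPI is a single-imputation method: its reported SE does not carry
  imputation uncertainty (by design, matching its single-dataset recipe);
  MIMP methods carry it through Rubin's rules.
* The iterative proximity imputers are fixed-point iterations of a
  stochastic map; results depend (mildly) on the forest seeds, which are
  exposed in `impute_control()`.
* Linearized SEs ignore propensity-estimation uncertainty; for ATE weights
  from a correctly specified logistic model this is conservative on
  average, but the calibration can degrade under misspecification.
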
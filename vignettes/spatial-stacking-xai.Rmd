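---
title: "Methods: spatial exploration, stacked ensembles and model-agnostic explanation for county mortality rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial exploration, stacked ensembles and model-agnostic explanation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

geostackx models a continuous areal health outcome — the motivating case
is a county-level age-adjusted mortality rate per 100,000 — from a panel
of behavioural, socio-economic, demographic and environmental risk
factors, and then explains the fitted model both globally and unit by
unit over the map. This vignette records the methods, their assumptions,
and the design decisions taken where the methodology is genuinely open.

## The analysis flow

1. **Exploratory spatial statistics.** Getis-Ord Gi* locates hot and
   cold spots of the outcome; the seven-level Gi-bin classification of
   its z-scores later serves as sampling strata. Bivariate local
   Moran's I relates the outcome at a unit to the neighbourhood average
   of a risk factor. The geodetector q-statistic quantifies how much of
   the outcome's variance a stratification by each factor explains.
2. **Stratified splitting.** Units are partitioned 70/15/15 into
   train/validation/test within each Gi-bin, so all three partitions
   carry the same spatial-cluster composition.
3. **Stacked generalization.** Five base-learner families (penalized
   linear, random forest, two gradient-boosting variants, a single
   hidden-layer perceptron) are tuned by random grid search under shared
   K-fold cross-validation; their honest out-of-fold predictions train a
   ridge meta-learner. Either every tuned candidate enters the stack
   ("all models") or only the best per family ("best of family").
4. **Evaluation.** MAE, RMSE and the observed-versus-predicted R²
   per partition, plus a bootstrap bias-variance decomposition.
5. **Explanation.** Permutation feature importance; partial-, local- and
   accumulated-local-dependence profiles; two-variable partial
   dependence for interactions; and additive break-down attributions,
   applied per unit to produce contribution surfaces over the map.
6. **Spatial regression baselines.** Maximum-likelihood spatial lag and
   spatial error models and geographically weighted OLS provide the
   classical comparison fits.

## Statistics implemented

**Gi\*.** For unit \(i\) with weights \(w_{ij}\) (binary, self
included — the "star" convention),
\[
G_i^* = \frac{\sum_j w_{ij}x_j - \bar X \sum_j w_{ij}}
  {S\sqrt{\bigl[n\sum_j w_{ij}^2 - (\sum_j w_{ij})^2\bigr]/(n-1)}},
\qquad S = \sqrt{\tfrac1n\sum_j x_j^2 - \bar X^2}.
\]
Gi-bins use the classical two-sided normal cutoffs 1.645/1.960/2.576
with no false-discovery-rate correction; both conventions (self weight,
no FDR) are defaults that can be overridden, since practice varies
across GIS tools. A zero-variance field yields all-zero scores with a
warning rather than NaNs.

**Bivariate local Moran.** \(I_i = z_{x,i}\sum_j w_{ij} z_{y,j}\) with
z-scored variables and row-standardized weights without self. Inference
is by conditional permutation (default 999 draws, seeded): unit \(i\) is
held fixed and the remaining \(n-1\) values of \(y\) are permuted, with
the two-sided pseudo p-value \((\#\{|I^{perm}|\ge|I^{obs}|\}+1)/(n_{perm}+1)\),
whose floor is \(1/(n_{perm}+1)\).

**q-statistic.** \(q = 1 - SSW/SST\), the one-way analysis-of-variance
share of variance explained by a stratification. The sum-of-squares form
sidesteps the sample-versus-population variance ambiguity of the
\(\sigma_h^2\) notation. Significance uses the noncentral-F reference
\(F = \frac{N-L}{L-1}\frac{q}{1-q}\) with
\(\lambda = \bigl[\sum_h \bar y_h^2 - (\sum_h\sqrt{N_h}\,\bar y_h)^2/N\bigr]/\sigma^2\);
the first term is deliberately unweighted by stratum size, so that
\(\lambda\) vanishes for homogeneous stratum means with equal sizes — a
size-weighted first term would grow like \(N\bar y^2/\sigma^2\) and push
every p-value to 1 for outcomes with a nonzero mean. Continuous factors
are discretized into five quantile strata by default (ties resolved to
the lower stratum, deterministically); categorical factors are used
as-is.

## The stacked ensemble

`stack_ensemble(formula, data)` is the single fitting entry point and
returns a classed object with `predict`, `print`, `summary`, `coef`,
`fitted` and `residuals` methods. Internally:

- **Shared folds.** One seeded fold assignment (default tenfold) is
  used for every learner, so out-of-fold meta-features are comparable
  across candidates and the meta-learner never sees a prediction made
  by a model trained on the same row.
- **Random grid search.** Each family samples up to `budget`
  hyperparameter combinations without replacement. Default grids are
  seeded with hyperparameter values reported as optima in comparable
  county-scale mortality studies (random forest 576 trees, depth 30,
  sample rate 0.6; gradient boosting 500 rounds, column sample 0.5,
  depth 20; extreme gradient boosting 350 rounds, depth 3, minimum
  child weight 50, column sample 0.75; elastic net \(\alpha = 0\),
  \(\lambda = 1\)) but are tunables, not assertions.
- **Early stopping.** Boosted learners monitor the held fold and stop
  once the relative RMSE improvement falls below 0.001 for 2
  consecutive rounds; the full-data refit uses the median stopped round
  across folds. The tolerance/rounds pair is recorded in each model
  card.
- **Meta-learner.** Ridge-regularized least squares with an unpenalized
  intercept; the default penalty (1e-6) exists only to absorb the
  near-collinearity that is routine among base-learner predictions and
  never changes a well-posed solution materially. A non-negative-weights
  switch is provided for users who prefer convex combinations; it is off
  by default because the choice between the two is not settled practice.
- **The perceptron family** is a single-hidden-layer network (nnet)
  with standardized inputs and response; deep multi-layer architectures
  are outside its scope and the family is therefore the one optional
  member of the panel.

## Evaluation

MAE and RMSE follow their defining formulas; the goodness of fit is the
R² of the simple regression of observed on predicted values (the squared
Pearson correlation, affine-invariant). The bias-variance decomposition
rebuilds the model on seeded bootstrap draws of the training pool
(default ten rebuilds) and reports, averaged over evaluation points,
\(\text{bias}^2 = (\bar{\hat f}(x) - f(x))^2\) and
\(\text{Var} = \overline{\hat f(x)^2} - \bar{\hat f}(x)^2\). Squared
bias is used throughout — the additive error identity
\(\text{Err} = \text{bias}^2 + \text{Var} + \sigma^2\) requires it, and
an unsquared "bias" term in that identity is treated as a notational
slip, not a different estimand. When the true surface is unknown, bias
is measured against observed responses and labelled accordingly (it then
absorbs the irreducible noise). Two caveats the tests encode: the
decomposition closes only as well as the evaluation set pins down the
noise term (relative error \(\sqrt{2/n_{test}}\)), and conditional on a
single training pool the bootstrap-average fit retains that pool's
sampling error, so the bias² of even an unbiased estimator is of the
same order as the bootstrap variance — unbiasedness is asserted as
bias² being a negligible share of total error, not of variance.

## Explainers

All explainers are pure functions of (model, data, seed) and accept any
object with a `predict(object, newdata)` method or a bare prediction
function.

- **Permutation importance** reports drop-out loss (RMSE after a
  feature's column is permuted) as both a ratio to and a difference from
  the baseline, averaged over seeded repeats, with the Monte-Carlo
  spread attached.
- **Profiles.** PD is the marginal average prediction on an empirical
  quantile grid (default 51 points); LD conditions each grid point on
  the nearest fraction of rows (default 0.25); AL accumulates mean
  within-interval finite differences over quantile intervals (default
  20) and is mean-centred under the empirical interval weights, making
  it unbiased under correlated features. Categorical features are
  profiled per level (PD only, unless a level order is declared). Empty
  AL intervals are merged with a neighbour and noted.
- **Break-down** decomposes one prediction into an intercept (mean
  reference prediction) plus per-feature deltas by sequential
  conditioning; additivity holds exactly by telescoping. The default
  ordering is greedy (largest absolute change in expected prediction at
  each step, ties broken lexicographically for determinism).
- **Attribution maps** run break-down per unit. The default is a single
  fixed order — ranked by global permutation importance — because
  per-unit greedy orders make columns incomparable across the map;
  greedy mode is retained for per-unit plots and flagged. Expectations
  use the full reference table by default with a seeded subsample as a
  speed knob (the subsample changes the reference distribution, not the
  additivity identity).

## Spatial regression baselines

The lag model \(y = \rho Wy + X\beta + \varepsilon\) and error model
\(y = X\beta + u,\ u = \lambda W u + \varepsilon\) are fitted by maximum
likelihood, concentrating over the autoregressive parameter with the
exact dense log-determinant \(\log|I-\rho W| = \sum_i \log(1-\rho\,\mathrm{ev}_i)\).
Because row-standardized weights built from a symmetric binary relation
are similar to a symmetric matrix, the eigenvalues come from a fast
symmetric decomposition; a dense nonsymmetric solver is the fallback.
This exact approach is intentional for desk-scale problems (a few
thousand units); sparse log-determinant approximations are out of scope.
GW-OLS uses a Gaussian kernel \( \exp(-d^2/2b^2) \) — the kernel family
is a fixed choice, as practice does not agree on one — with the
bandwidth selected by leave-one-out cross-validated RMSE over a
geometric grid from the median nearest-neighbour distance to the extent
diagonal; cross-validation was preferred over AICc as the simpler
criterion to state and test.

## The synthetic study area

The generator exists so that every stage has a testable ground truth;
it emulates the statistical *shape* of a national county table, not any
real joint distribution.

- **Geometry.** A regular `nrows x ncols` lattice of square units
  (default 40x40 = 1600 units, the scale of recovery tests).
- **Covariates.** Independent white-noise fields smoothed by a Gaussian
  kernel (scale `spatial_range`, default 4 cells) and rescaled to
  plausible ranges (smoking 5-45%, poverty 5-50%, PM2.5 4-15 µg/m³,
  elevation 0-2500 m, ...). Kernel smoothing was chosen over SAR/CAR
  simulation because the single range parameter is interpretable and
  the induced autocorrelation is directly checkable with Moran's I
  (near 0 as the range shrinks, above 0.5 for ranges of several cells
  on a 40x40 map). Categorical factors (radon zone, urban-rural class,
  coal presence) slice an auxiliary smoothed field at quantile breaks,
  so levels are spatially coherent and all levels appear on maps of
  20x20 and larger.
- **Response.** `intercept + additive effects + threshold interaction +
  categorical offsets + N(0, noise_sd)`. The default surface is
  calibrated qualitatively to the county-mortality literature: positive
  smoking (dominant, 1.0 per percentage point), poverty (0.15), PM2.5
  (0.8), percent white (0.08); negative elevation (-0.01 per metre) and
  percent Hispanic (-0.15); poverty gains an extra 0.35 per point only
  where smoking exceeds 30% (the threshold interaction); noise SD 6
  rate units, comparable to the hold-out errors such models attain. The
  intercept (50) keeps the default surface nonnegative; no clipping is
  applied by default so additivity diagnostics remain exact, and a clip
  option exists for users who want a hard floor.
- **Truth storage.** The noiseless surface and per-feature effect
  functions are attached as attributes, so profile and attribution
  tests compare against analytic truth rather than refitted estimates.

What passing tests on this generator do *not* show: robustness to the
dependence structure of real covariates (generated fields are mutually
independent), to missingness (none is generated), or to the
irregular geometry and population weighting of real county maps.

## Numerical choices and degenerate inputs

- Zero-variance fields: Gi* returns zeros with a warning; the
  q-statistic and the observed-versus-predicted R² refuse constant
  inputs explicitly.
- Quantile discretization resolves boundary ties to the lower stratum;
  greedy break-down breaks ties lexicographically; largest-remainder
  rounding fixes split counts — all three make reruns bit-identical.
- Strata smaller than the number of partitions go wholly to training
  with a warning rather than failing the split.
- glmnet requires two columns; single-feature designs are padded with a
  zero column internally.
- Every stochastic function takes a `seed` and restores the caller's
  RNG state; the pipeline derives per-stage seeds from one root seed so
  stages are independently reproducible.

## Problem sizes

The test suite and the reproduction script run the pipeline at 30x30
(900 units) and recovery checks at 40x40 (1600 units), with reduced
learner grids (two candidates per family, fivefold cross-validation,
three tree families) — sizes chosen so the full suite exercises every
claim at honest scale on a single workstation core. The fitting
defaults themselves (tenfold cross-validation, five families, larger
grids) reflect full-study practice.

## Known limitations

- Permutation inference for local Moran uses an R-level loop over
  units; on maps beyond ~10^4 units it becomes the slow step.
- The dense eigenvalue log-determinant limits the spatial lag/error
  fits to a few thousand units.
- Greedy break-down is quadratic in the number of attributed features;
  fixed-order maps are linear and are the default for that reason too.
- The q-statistic's noncentral-F p-values are asymptotic; no permutation
  fallback is provided.
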
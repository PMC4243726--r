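---
title: "Mapping KIDSCREEN-10 onto CHU9D utilities: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping KIDSCREEN-10 onto CHU9D utilities: models, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chu9dmap)
```

## The problem

The KIDSCREEN-10 is a widely used 10-item health-related quality of life
(HRQoL) questionnaire for children and adolescents, but it is not
preference-based: its summary score cannot be used to compute
quality-adjusted life years (QALYs). The Child Health Utility 9D (CHU9D) is
preference-based — each health state carries a utility between 0.33 (worst
state, Australian adolescent tariff) and 1 (full health) — and therefore
supports cost-utility analysis. When a study administered only the
KIDSCREEN-10, a *mapping* (crosswalk) algorithm predicting CHU9D utilities
from KIDSCREEN-10 responses is the second-best route to QALYs.

`chu9dmap` does two things:

1. **Applies the published mapping algorithms** — sixteen coefficient sets
   (two CHU9D value sets x four estimators x two model forms), packaged as a
   registry and applied with the standard truncate-at-one adjustment.
2. **Re-implements the estimation pipeline** that produced them, so the same
   workflow — four estimators, forward stepwise selection, bootstrap
   selection frequencies, VIF diagnostics, MAE/RMSE goodness of fit, 5-fold
   cross-validation and random-subsample validation — can be run on any
   paired dataset.

## The two model forms

With `KS` the KIDSCREEN-10 index (a T-score, mean approximately 50, SD
approximately 10) and `KS_Ij` the raw item scores (1–5, higher = better
HRQoL on every item):

* **Model 1 (index form):** `CHU9D = alpha + beta1*KS + beta2*KS^2`. The
  quadratic term captures the concave relationship between the instruments.
  Under the fractional-logit estimator the link function supplies the
  curvature and the squared term is dropped.
* **Model 2 (item form):** `CHU9D = alpha + sum_j gamma_j * KS_Ij` over a
  stepwise-selected item subset. This is the preferred published form; the
  flagship algorithm (`"AU/MM/model2"`) uses six items (I1 fit and well, I2
  energy, I3 sad, I4 lonely, I9 school, I10 attention).

Age and gender are supported as optional covariates but are excluded from
the packaged equations (they were not significant in the source analysis).

Identity-link predictions are unbounded, so predictions for respondents near
full health can exceed 1. The standard adjustment truncates predictions
above 1 to 1; for any record with observed utility at most 1 this can never
increase the pointwise error, hence never worsens MAE or RMSE (a theorem the
test suite verifies by property checks). Lower truncation at the value-set
floor is available but off by default, matching published practice.
Predictions are intended for group-level (mean) use; individual-level
predictions carry substantial error.

## The four estimators

All four are implemented in this package and return
heteroskedasticity-robust standard errors with Wald p-values:

* **OLS** — QR least squares; HC1 sandwich standard errors; `r_squared`
  reported.
* **CLAD** (censored least absolute deviations) — median regression robust
  to the utility ceiling at 1. The inner LAD problem is solved *exactly* by
  descent through basic solutions of the LAD linear program: an optimal LAD
  fit interpolates `p` observations; the exact minimiser along any edge is a
  weighted median of residual/slope ratios; descending until no edge
  improves reaches the global optimum of the convex piecewise-linear
  objective. Ties (e.g. the even-`n` median) resolve to the lower weighted
  median. CLAD then iterates the standard trimming scheme: fit LAD, retain
  observations with fitted values at or below the censor point, refit until
  the retained set is stable (non-convergence after `max_iter` is flagged,
  not fatal). Standard errors come from a seeded nonparametric bootstrap of
  respondent records (`B = 200` by default; no asymptotic CLAD variance
  formula is in common use, and pairs bootstrap is the standard convention).
* **MM** — two-stage robust regression: a 50% breakdown S-estimate of scale
  (Tukey bisquare, tuning constant 1.5476) computed by the fast-S algorithm
  over seeded random p-subsets (500 by default, two one-step refinements
  each, the best five refined to convergence), followed by an IRWLS M-step
  with the bisquare tuned to a requested Gaussian efficiency (c = 4.685 at
  the default 95%; the constant is solved numerically from the efficiency
  integral for other values) holding the S-scale fixed. If the M-step fails
  to improve the robust objective the S-estimate is returned and flagged.
  Standard errors are the heteroskedasticity-robust M-sandwich.
* **Fractional logit** — quasi-binomial IRLS with logit link applied
  directly to utilities in (0, 1], with the robust GLM sandwich. No
  rescaling of the 0.33–1 range is applied: applying the inverse logit on
  the raw utility scale is what reproduces the published extrema exactly.
  With the canonical link and an intercept, the fitted mean equals the
  observed mean to solver precision — the reason this estimator reproduces
  observed mean utilities perfectly at the group level.

Numerical choices: coefficient-change tolerances default to 1e-8 (IRWLS) and
1e-11 on the LAD objective; the LAD vertex descent caps iterations at
`max(200, 10n)`; rank-deficient designs are refused with the collinear term
named, except inside stepwise selection where an exactly collinear candidate
simply cannot enter. Record order never moves a deterministic estimator;
for MM the random p-subsets depend on row order, but a converged M-step
lands on the same fixed point to well below reporting precision.

## Selection and validation

* **Forward stepwise** (per estimator, entry threshold p < 0.05 on the
  robust Wald p-value; earlier candidate wins exact ties). Selection is run
  independently per estimator because different estimators legitimately
  retain different item subsets.
* **Bootstrap stepwise** — `B` pairs-bootstrap resamples, counting how often
  each item is selected; a stability ranking of the items.
* **VIF** — `1/(1 - R^2_j)` per item; perfect collinearity reported as
  infinite, not an error.
* **Validation I** — seeded 5-fold cross-validation: the stepwise selection
  and the fit are repeated on each 80% estimation sample, utilities are
  predicted for the held-out 20%, and all `n` held-out errors are pooled
  into one MAE/RMSE. MAE is the headline criterion (RMSE reported
  alongside).
* **Validation II** — the full-sample algorithm applied to seeded random
  subsamples (100/300/500 by default) drawn without replacement.

Fold assignment is a seeded uniform shuffle followed by a block split (group
sizes differ by at most one); the seed is a required argument everywhere
randomness enters, because the original analysis seeds are unknown.

## The synthetic-data generator

The respondent-level estimation sample (n = 590) is not publicly deposited,
so the package ships a generator that emulates its published statistical
structure; all estimator and validation machinery is exercised against it.

* **Items:** latent standard-normal propensities for the ten items with a
  one-factor correlation structure (loadings 1.8 x the target item–utility
  correlations, capped at 0.9), discretised at fixed thresholds (cumulative
  level probabilities 0.03/0.10/0.25/0.55) giving the left-skewed item
  distributions of a relatively healthy community sample.
* **Utility:** a linear combination of the standardised items plus Gaussian
  noise, scaled and shifted so that after clipping to [0.33, 1] the observed
  utility has mean 0.808, SD 0.155 and a ceiling mass of 0.15 at full
  health. The three conditions are mutually consistent for a normal latent
  utility (ceiling quantile k = 1.0364 implies latent mean 0.8218 and SD
  0.1774). The combination weights are solved from the target item–utility
  correlations (0.488 down to 0.175) using the *exact* correlation matrix of
  the discretised items (bivariate-normal rectangle probabilities by
  numerical integration) and a Stein-type de-attenuation for the ceiling
  clip. At n = 5000 the empirical moments land within 0.01 and the
  correlations within 0.05 of their targets.
* **Index:** an affine calibration of the raw sum to mean 43.737 / SD 7.932.
  A Rasch lookup is not used — the index model only needs a monotone index
  with the right first two moments, and the official person-parameter table
  is manual-bound (a user-supplied table loader is provided instead).
* **Truth:** the generating intercept, per-item coefficients and noise SD
  are returned with every dataset, enabling Monte-Carlo recovery studies
  (`recovery_harness()`), including contamination scenarios for robustness
  checks and a fractional (beta-noise, logit-mean) response regime for the
  fractional-logit estimator.

Design notes, made once and fixed: the ceiling mass 0.15 is not published
(the density plot shows "a large number" of responses at 1) and was chosen
so truncation behaviour is clearly visible; it is config-exposed. The
one-factor structure was chosen over equicorrelation because equicorrelated
items force the weakest-correlated item into a large *negative* partial
coefficient — the opposite of the published pattern in which all significant
item coefficients are positive and the weakly correlated items are the ones
stepwise drops. Under the one-factor default the generating coefficients
are all positive, bootstrap-stepwise ranks the strong items (I1/I3/I10) at
the top and the weakest (I6) at the bottom, and the mean VIF lands near 1.7
(scalar `latent_cor = 0.59` reproduces the published mean VIF of 1.88
instead, at the cost of the selection structure). The generator emulates
published *summary* structure only: it does not model Rasch response
processes, differential item functioning, or the real joint distribution of
items and utilities, so passing recovery tests demonstrates correctness of
the estimators under the declared conditions, not performance on real
respondents.

What a correctly specified estimator must achieve on these conditions is
checked by Monte-Carlo: 200 replicates at n = 590 for coefficient recovery
(bias within twice the replicate SD), a ceiling-censoring comparison in
which CLAD's slope bias is smaller than OLS's, and a 20% gross-contamination
scenario in which MM stays within three clean-data SDs of the truth while
OLS departs by dozens. These replicate counts are the package's declared
study sizes for its own verification and keep the full suite in the
low minutes on one core (the MM fast-S stage uses 100 subsets inside the
replicate loops; its default elsewhere is 500).

## Reading the published registry

The registry JSON stores coefficients as decimal strings exactly as printed,
avoiding any float-transcription drift; `chu9d_algorithm()` parses them on
load, and serialised specs round-trip exactly. Two transcription caveats are
recorded in the registry itself: the UK Model 2 table's flattened layout
leaves one item coefficient (0.012365 on item 10) ambiguous between the CLAD
and MM columns — it is assigned to MM by column order and flagged with a
`provenance` note — and no published maximum is pinned to the CLAD
algorithms, whose all-fives evaluation does not reconcile exactly with the
printed extremum.

## Known limitations

* Dataset-dependent published statistics (MAE 0.0946, RMSE 0.1193, R^2
  0.36/0.41, Table-level means) cannot be reproduced without the original
  sample; the synthetic pipeline reports the same quantities under declared
  conditions instead.
* The official KIDSCREEN-10 norm-table scoring is out of scope; the index is
  supported via a user-supplied Rasch table or the raw-sum passthrough.
* Mapping runs one way (KIDSCREEN-10 to CHU9D); no uncertainty intervals
  accompany individual predictions, which are not recommended for
  individual-level use in any case.
* Complete cases only; no imputation.
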
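---
title: "Resampling-based identification of relevant intersections in smoking-cessation outcomes"
author: "intersmoke authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling-based identification of relevant intersections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intersectionality research asks whether combinations of demographic and
socio-economic attributes (say, young, female, highly educated) relate
to a health outcome differently than the sum of their parts.
Statistically that is a question about interaction terms, and the naive
approach — stratify on everything and compare cells, or throw every
pairwise interaction into one regression — is notorious for producing
irreproducible findings: categorising continuous covariates inflates
spurious effects, and testing many interactions at once overfits.  A
full cross-stratification of sex, a three-level age grouping,
education, income and region would need 2 x 3 x 3 x 3 x 3 = 162 cells
(`count_full_strata()`), most of them too sparse to estimate anything.

This package implements a guarded alternative for two smoking-cessation
outcomes measured in a cross-sectional adult smoker survey:

* **Motivation to stop smoking**, a 7-level ordinal scale collapsed to
  three analysis categories — *absence* (level 1), *unspecific*
  (levels 2–3) and *motivation* (levels 4–7) — and modelled by
  multinomial logistic regression (the proportional-odds assumption of
  an ordinal model fails for these data; the Brant test in the pipeline
  documents this).
* **Past-year quit attempt**, the count of serious attempts in the last
  12 months dichotomised to any-vs-none and modelled by binary logistic
  regression.

The guardrails are: continuous covariates (age, standardised net
household income) enter through restricted cubic splines instead of
categories; candidate models, differing in functional forms and in at
most a small number of interaction terms, are compared by
*out-of-sample* prediction accuracy under bootstrap resampling; and a
winning interaction must additionally survive a likelihood-ratio test.
Missing data are handled by multiple imputation, run separately for
learning and validation data, with Rubin's rules for pooling.

## The synthetic cohort

The survey data themselves are third-party and not redistributable, so
the package ships a generator (`generator_config()`,
`simulate_survey()`) whose defaults emulate the published learning-data
margins; every downstream stage is tested against it.

* **Age** is drawn from a truncated normal on [18, 99]; the underlying
  location and scale are solved numerically at configuration time so
  the *realised* mean and SD match the targets (46.8, 16.7).  A naive
  truncation of N(46.8, 16.7²) would inflate the mean by about 1.6
  years.
* **Income** (standardised 0–7 per household member) uses a
  moment-matched gamma distribution truncated to [0, 7]: the published
  margins give mean 1.47, SD 0.818, median 1.39 < mean, and the gamma
  reproduces that right skew with no extra parameters.
* **Sex, education, region, urges to smoke** are categorical draws at
  the published proportions; **year** is uniform over 2016–2020;
  96.5% of records are current smokers, the rest recent ex-smokers.
* The **motivation outcome** is drawn from a 3-category multinomial
  model whose default log-odds are the published odds-ratio table for
  urges, year, sex, education and region.  Age enters through a 4-knot
  restricted cubic spline fitted (least squares, at configuration
  time) to the published age contrasts, and the whole age effect is
  multiplied by `1 + s * income` with `s = -0.35` for the motivation
  category: this is the age x income interaction surface, built so the
  probability of motivation peaks between ages 30 and 50 for low and
  middle incomes and flattens as income grows.  No numeric surface is
  published, only its qualitative shape; the scale parameters are
  declared defaults, exposed in the config.  The collapsed category is
  then expanded to the 7-level scale with conditional proportions taken
  from the published level frequencies, and recent ex-smokers are set
  structurally missing (the scale is not assessed for them).
* The **quit-attempt outcome** is a logistic draw whose default
  coefficients are the published odds ratios, including the sex x
  education interaction (female:high OR 0.67) and a time trend of 0.77
  per year.  The published age odds ratio of 0.95 carries no unit; the
  default interprets it per decade, since 0.95 per single year would
  halve the odds across 14 years of age — far steeper than the gentle
  published probability gradients.  The interpretation is a config
  field, not a constant.
* **Intercepts** for both outcomes are calibrated numerically (Newton
  on a fixed internal covariate draw of 20 000 records) so that the
  marginal outcome frequencies match the published margins: 47.9%
  absence among current smokers with observed motivation, 18.3% with at
  least one quit attempt.  Calibration is skipped when the user supplies
  intercepts explicitly.
* **Missingness** is injected by per-variable logistic models.  Rates
  default to the published missing fractions (education 1.4%, urges
  1.2%, quit attempts 4.6%, income ~0%; motivation 1.4% among current
  smokers, which together with the structural ex-smoker gap reproduces
  the published 4.8% among all past-year smokers).  Men with high
  education get a +0.5 log-odds increment on the smoking-habit
  variables, reproducing the published selectivity; the intercept of
  each model is solved so the marginal rate stays on target.  Because
  the probabilities are computed on the pre-deletion table, the
  mechanism is missing-at-random given observed covariates.

What the generator does **not** emulate: the bi-monthly wave structure,
survey weights, non-response patterns beyond the MAR mechanism above,
measurement error, or any pandemic-era shift.  Tests passing on this
cohort therefore demonstrate that the *pipeline* behaves correctly
under known truth — recovery of configured effects, calibrated error
rates, stable validation — not that the published effect sizes would be
recovered from the real survey.

## Restricted cubic splines

`place_knots()` uses the standard quantile placements (0.10/0.50/0.90
for 3 knots; 0.05/0.35/0.65/0.95 for 4; 0.05/0.275/0.50/0.725/0.95 for
5) with the linear-interpolation (type-7) quantile estimator.
`rcs_basis()` evaluates the restricted truncated-power basis, linear
beyond the boundary knots and C² everywhere; the nonlinear columns are
divided by `(t_k - t_1)^2` so they stay on a scale comparable to the
linear column (this rescales coefficients, never fitted values).  Knots
are computed on learning data and frozen into the model specification
(`freeze_spec()`), so validation-data design matrices use the identical
basis — without this, external validation would silently change the
model.  Odds-ratio contrasts for spline-coded covariates
(`evaluate_contrast()`) compare eta(v) to eta(reference) with a Wald
interval from the linear-combination variance; values outside the
observed range are flagged as extrapolation into the linear tail.

The pipeline default is 4 knots, with 3–5 available in the candidate
space; the number of knots is part of what the bootstrap selection
searches over.

## Model fitting

Binary logistic models go through iteratively reweighted least squares
(`stats::glm.fit`) run to epsilon 1e-12; the multinomial model is fitted
by a Newton–Raphson routine written for this package, with the
reference category's linear predictor fixed at zero, step-halving, and
convergence when every score coordinate is below 1e-8 or the relative
log-likelihood change is below 1e-10.  Both report the inverse observed
information as the covariance.  Possible separation — a coefficient
exceeding 15 on standardised columns — is flagged with a warning but
not penalised; constant columns (the intercept) are excluded from that
check.  Numerically singular information matrices (which arise in
sparse bootstrap or imputation draws) fall back to a tiny ridge.
Within each imputed data set, fitting is complete-case: imputation is
the missing-data mechanism, and residual missing rows (the structurally
unassessed motivation of recent ex-smokers) are excluded.

Year enters the motivation model as a categorical covariate (matching
the published per-year contrasts) and the quit-attempt model as a
linear trend (matching the single published per-year odds ratio); both
forms are available in `model_spec()`.

## Multiple imputation

`chained_imputation()` runs chained equations with, per variable type:
predictive mean matching for continuous variables (5 donors, type-1
matching, residual-variance and coefficient draws from the approximate
posterior), logistic draws for the binary outcome, multinomial draws
for education, region, urges and the collapsed motivation category.
The conditioning set is all intersectionality measures, the urges
confounder, year, and both outcomes; the motivation outcome, usable as
a predictor despite its structural gap, carries an explicit
"not assessed" level for recent ex-smokers.  Each of the m imputations
is an independent chain (10 iterations by default) seeded
deterministically from the master seed.  The collapsed 3-category
motivation variable is imputed rather than the 7-level scale: the
analysis model only ever sees the collapsed outcome and the sparse top
levels would destabilise a 7-category draw.  Chain non-convergence is
not detected — a documented limitation; with the low missingness rates
of this design (< 5% per variable) 10 iterations is conventional.

Learning and validation data are imputed in fully separate runs with
separate seeds, so no validation information reaches the learning
models.

Scalar pooling (`pool_scalar()`) follows Rubin's rules with
Barnard–Rubin degrees of freedom.  Likelihood-ratio tests are pooled by
the Meng–Rubin statistic (`pool_lr()`): average the complete-data LR
statistics, re-evaluate the LR at the pooled coefficient estimates, and
refer their combination to an F distribution.  With identical completed
data sets this reproduces the single-data-set test exactly.  One
caveat worth knowing: when the variable carrying the missingness is
itself a member of the tested interaction and the imputation model
contains only main effects, the imputed values dilute the interaction
signal and the pooled test becomes conservative — the well-known
congeniality requirement.  The type-I calibration experiment in the
test suite therefore places missingness on a main-effect covariate
(income); an analyst imputing data for an interaction analysis should
include the relevant product terms in the imputation model.

## Scoring rules and diagnostics

The **Brier score** is the mean squared distance between the binary
outcome and its predicted probability.  The **polytomous discrimination
index** (PDI) generalises discrimination to K categories: draw one
observation from each category; the category-j component is the
probability that the observation truly in category j receives the
strictly highest predicted probability for category j; the PDI averages
the K components.  Ties among t observations sharing the maximum are
credited 1/t — under this convention uniform predictions score exactly
1/K, a clean calibration point.  The implementation counts, per
category, how many members of every other category fall below each
value (sorted vectors and `findInterval`), which is O(n log n) per
category; the test suite checks it against exhaustive tuple enumeration.

The **Brant test** fits the J-1 cumulative binary models, assembles the
joint covariance of the stacked slopes, and Wald-tests slope equality
across splits — globally and per variable.  The pipeline runs it on
both the 7-level and the collapsed 3-level motivation scale as the
diagnostic that motivates the multinomial (rather than ordinal) model.

**Accuracy change** between learning and validation data is reported as
a percentage: for the PDI, `100 (PDI_L - PDI_V) / PDI_L`; for the Brier
score the comparison is made on the accuracy scale `1 - Brier`.  The
published comparison reports a single accuracy-reduction percentage per
outcome without defining the transformation; mapping the Brier score to
`1 - Brier` is this package's declared convention, configurable at the
call site.

## Bootstrap out-of-bag selection

`enumerate_candidates()` crosses the allowed functional forms of the
continuous covariates with interaction subsets (at most one interaction
by default — both published final models contained exactly one; the
limit is configurable).  `bootstrap_select()` then draws B bootstrap
samples of the learning data; each sample is inner learning data, its
out-of-bag complement inner validation data.  Every candidate is fitted
on the sample and scored out-of-bag, scores are averaged over imputed
data sets and then over replicates, and the best mean score wins
(highest PDI / lowest Brier).  Replicates in which a factor level or an
outcome category is absent from the sample (or from the out-of-bag part,
for the PDI) are redrawn up to 10 times, then skipped and logged;
candidates whose fits fail in a replicate get no score there.  The same
bootstrap draws are shared by all candidates, so comparisons are
paired.  Selection is deterministic given the seed.

For the quit-attempt outcome the pipeline first settles the functional
forms of the continuous covariates by backward elimination under pooled
BIC (`backward_eliminate()`) — removals honour the hierarchy
(interactions before their main effects, splines reduced to linear
before a covariate may be dropped, protected base terms never
dropped) — and then searches the interaction pool at those forms by
bootstrap Brier scoring.  Interactions are deliberately *not* subjected
to the BIC criterion itself: with n around 9000 a two-parameter
interaction must improve the deviance by 2 ln(n) ≈ 18 to survive BIC,
which no interaction of epidemiologically plausible size achieves, so a
strict BIC gate on interactions would make the whole search pointless;
the out-of-bag score plus the confirmation test are the arbiters.  For
the motivation outcome, where stepwise machinery is unavailable, the
space is searched exhaustively (`best_subset()`).  Finally `confirm_interaction()` tests any winning
interaction against the same model without it via the pooled LR test at
alpha = 0.05; a winner without interactions passes vacuously.

The default B is 200.  Published descriptions of this strategy speak of
training on thousands of replicates on a compute cluster; 200 keeps a
desk-scale run in minutes, and the experiments in the test suite use
B = 50 with n = 9000 — at that effect size (interaction OR 0.67) the
selection frequencies are already stable, as the suite's
detection/suppression experiment shows.

## Pooled effects and external validation

`pooled_or_table()` pools each coefficient across imputations on the
log-odds scale and exponentiates afterwards (never the reverse);
spline-coded covariates are reported as contrasts at chosen values
against a reference.  `marginal_probabilities()` computes average
marginal predictions: for each grid cell the grid covariates are set to
the cell values for *every* record and predictions are averaged over
the empirical distribution of the remaining covariates — this is
marginal standardisation, matching probability-surface figures, rather
than prediction at covariate means (which answers a different
question about a single "average" person); confidence intervals pool
delta-method variances across imputations on the logit scale to respect
the [0, 1] range.  `external_validate()` refits the winner on each
learning imputation, averages the coefficients, predicts every
validation imputation with the frozen knots, and reports the accuracy
change.

## Numerical and design choices, in brief

* Split sizes use round-half-to-even of `n * fraction` (so 13 245 at
  70% gives 9272/3973).
* Ties in selection resolve to the first candidate in enumeration
  order (`which.max`/`which.min`), which is deterministic.
* Ridge fallback for singular information: 1e-6 relative to the mean
  diagonal, used only when an exact solve fails.
* Degenerate inputs error early with configuration/domain messages:
  non-sum-to-one proportions, unordered bounds, n = 0, mtss levels
  outside 1–7, fewer than 3 outcome levels for the Brant test, m < 2
  for imputation.
* Problem sizes in the test suite are desk-scale choices documented
  here: type-I experiments use 500 replicates at n = 500–2000 with
  m = 5 imputations; recovery uses one n = 50 000 cohort with m = 3;
  selection experiments use n = 9000, B = 50, 20 seeded runs per arm;
  the end-to-end stability check runs the full pipeline on 13 245
  records (9272/3973 split) with m = 2 per part, B = 50, across 10
  seeds.

## Limitations

The pipeline inherits the limitations of its ingredients: the bootstrap
selection compares only the candidates it is given; the BIC prefilter
can in principle drop an interaction that out-of-bag scoring would have
kept; D3 pooling assumes equal fractions of missing information across
the tested parameters and is conservative under uncongenial imputation;
and the synthetic cohort, however carefully calibrated, is a model of
published margins, not of the survey's full dependence structure.  One
empirical observation from the package's own runs: the categorical
sex x education interaction in the quit-attempt model is selected
reliably at n ≈ 9000, whereas the smooth age x income modulation of
the motivation model is often passed over by out-of-bag PDI scoring at
desk-scale B — discrimination-based selection is simply less sensitive
to a gradual damping of a spline surface than a likelihood-ratio test
would be, which is worth remembering when interpreting a winner
without interactions.
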
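---
title: "Methods: now-casting acute malnutrition prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: now-casting acute malnutrition prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nutcast)
```

`nutcast` predicts the prevalence of acute malnutrition among children 6–59
months old at the resolution of one administrative stratum and one calendar
month, from survey reanalysis on one side and a panel of routinely collected
predictors on the other. This vignette explains the statistical model, the
assumptions behind each stage, the defaults and why they were chosen, and
what the synthetic-data experiments do and do not demonstrate.

## The unit of analysis and the two data streams

Everything is keyed by (stratum, month). The *observed* side is a set of
cluster surveys, each representative of one stratum-month: child-level
weight, height/length, MUAC, age, sex and oedema. The *predictor* side is a
long panel of monthly series per stratum — conflict event and death rates,
rainfall, NDVI, market prices, terms of trade, epidemic case counts,
displacement, humanitarian presence — plus a static livelihood label and
population denominators used to convert counts to rates per 100 000.

## Survey reanalysis

Weight-for-height z-scores use the LMS transform
$z = ((w/M)^L - 1)/(L\,S)$ with the reference parameters linearly
interpolated at the child's height between tabulated keys; `read_lms_csv()`
accepts any reference in (sex, key, L, M, S) format. The packaged table
(`synthetic_lms_table()`) is *synthetic*: a smooth monotone median curve
with realistic magnitudes, intended for testing and simulation, not for
clinical use.

Exclusion flagging applies three rules in fixed order — missing, age
outside 6–59 months, |WHZ − centre| > 5 z — and always labels rather than
drops. Two centring conventions exist in field practice; the package
defaults to the survey's observed mean (the SMART convention) and exposes
`center = "reference_zero"` as the alternative. MUAC values are not subject
to the z-flag; optional absolute plausibility bounds (80–220 mm) are
available but off by default, because the 5-z rule is defined for z-score
indices only. Oedema-positive children are never flagged on WHZ since their
case status does not depend on it.

Case definitions are strict-inequality cutoffs (WFH: SAM < −3 z,
GAM < −2 z; MUAC: SAM < 115 mm, GAM < 125 mm) with bilateral oedema
overriding to SAM; SAM ⊆ GAM holds by construction. Survey-level prevalence
is the kept-record case fraction; its uncertainty comes from an
intercept-only binomial fit with the sandwich covariance clustered on the
survey cluster, the design-based analogue for a cluster sample. A survey
with a single cluster falls back to the unclustered variance with a
warning; a survey with zero or all cases gets an exact
Clopper–Pearson-style bound because the logit-scale sandwich interval is
degenerate there.

Each survey carries an analysis weight: the ENA-style quality score,
linearly rescaled from "0 best … 0.5 worst" to `1 − 2·raw` ∈ [0, 1], times
the sampling coverage (the accessible fraction of level-3 units, e.g.
10/12). The weight multiplies the child count in all model fits, so
low-quality or frame-restricted surveys contribute less.

## Predictor engineering

Variables missing for ≥ 30 % of strata or ≥ 30 % of months are excluded
(both margin fractions are reported). Completion is hierarchical:
slowly varying service series are linearly interpolated in time (edges
extended from the nearest value); market price series borrow
0.7 × nearest market + 0.3 × mean of the other markets; whatever remains is
completed by chained-equations imputation — iterated normal-model
stochastic regression of each incomplete variable on the others,
deterministic given its seed, returning a single completed panel. Single
rather than multiple imputation is used because one completed panel is
what propagates into the modelling stage; the number of iterations
(default 10) and the seed are exposed.

Counts become rates per 100 000 using the stratum-month population. Two
derived families reduce stochastic noise: trailing 3-month rolling means
(value at t averages months t−2…t; trailing, not centred, so no future
information leaks into a now-cast) and cubic smoothing splines for price
variables (`spar = 0.6` by default — moderate smoothing; as the penalty
grows the fit tends to the least-squares line, which the tests use as a
guard against degeneracy; series with fewer than 4 observed points are
returned unsmoothed with a warning).

Features are windowed lag means: the mean of a variable over months
t−end…t−start prior to the reference month, with start ≥ 1 so that only
information available before the survey month is used. "Previous 3 months"
means t−1…t−3. Climate variables are conventionally offered the two
trimesters (1–3, 4–6) and the prior semester (1–6); other variables get
1–3, 2–4 and 4–6 by default. A global `forecast_offset` adds k months to
every window, turning the same machinery into a k-month-ahead forecaster;
the identity (offset 3 on window 1–3) = (window 4–6) is tested.

## The GLM track

Surveys are split chronologically: the first ~70 % to training, the most
recent 30 % to holdout, never splitting a month. Binary outcomes use a
quasi-binomial logit GLM, continuous outcomes (mean WHZ, mean MUAC) a
gaussian one. Fitting operates on survey × cluster aggregated rows (case
fraction, weight = children × survey weight); because features are
constant within a cluster this reproduces the child-level weighted fit
exactly — coefficients and clustered sandwich scores are identical — while
keeping all-subsets enumeration tractable.

Per predictor, the candidate forms are the continuous feature and a
categorical version cut at the weighted quartiles of the training
distribution (breakpoints are overridable per variable; quartiles are a
reproducible stand-in for the field practice of choosing breakpoints by
visual inspection). The form and lag with the smallest p-value against the
intercept-only model wins — a dispersion-scaled χ² deviance test for
quasi-binomial outcomes, an F test for gaussian ones; exact ties break
towards the continuous form, then the shortest lag. All non-empty subsets
of the selected specs (up to `max_terms`) are fitted; candidates are ranked
by MSE between their stratum-month predictions and the observed holdout
survey estimates, and the best 10 % (rounded up; ties to fewer terms, then
lexicographic) are shortlisted. Leave-one-survey-out cross-validation
refits the chosen candidate once per training survey; the left-out unit is
the whole survey, i.e. one stratum-month, and LOOCV is run for shortlisted
models only because all-subsets × LOOCV is combinatorially prohibitive.

Prediction intervals are parametric-simulation percentiles: coefficient
draws from a multivariate normal with the cluster-robust covariance,
response recomputed per draw (features are constant within a stratum-month,
so the stratum-month mean equals the single-row fitted response), 95 % and
80 % percentile intervals, deterministic given the seed (default 10⁴ draws;
the orchestrated pipeline uses 4 × 10³ to bound runtime). The robust
covariance is *not* additionally scaled by the Pearson dispersion: the
sandwich estimator already absorbs overdispersion, and scaling it again
would double-count; the dispersion is recorded on the model object. When
an interval for an *observed* survey estimate is wanted (e.g. coverage
calibration), `sampling_n` adds binomial sampling noise at the comparison
survey's size to each draw; without it the interval describes the latent
stratum-month prevalence. Cluster-robust errors cluster on
survey × cluster (clusters nested in surveys). Interactions are not
searched automatically; explicit interaction columns can be supplied as
features.

## The random-forest track

The RF track regresses the survey point estimates, aggregated one row per
surveyed stratum-month, on the same features: 1000 trees by default,
`mtry = ⌈p/3⌉` (the regression convention), survey weights as bootstrap
sampling weights, permutation importance, deterministic given the seed.
Prediction standard errors use the jackknife-after-bootstrap estimator
with Monte-Carlo bias correction; the infinitesimal-jackknife variant is
available via `se_method = "infjack"`, but in our calibration simulations
it systematically under-covered at realistic table and ensemble sizes,
while the jackknife-after-bootstrap variant was close to nominal, so the
latter is the default. Intervals are normal-theory point ± z·SE, truncated
to [0, 1] for prevalence outcomes; negative bias-corrected variances are
floored at zero with a warning.

## Evaluation

All metrics operate on inner-joined (prediction, observation) pairs per
stratum-month and source (train / LOOCV / holdout): MSE; relative bias
$\tfrac1n \sum_i (\hat y_i - y_i)/y_i$ with zero observations excluded
from the mean and counted separately (the formula divides by $y_i$);
relative precision, the mean ratio of the one-sided 95 % interval — taken
as half the CI width — to the point estimate; effective coverage, the
share of predicted points inside the observed survey's design-based CI
(closed interval, 95 % and 80 %); and sensitivity/specificity against the
humanitarian thresholds (SAM 2 %, 5 %; GAM 15 %, 20 %), using ≥ on both the
observed and predicted side and reporting the denominators, with `n/a`
when a denominator is empty. Report objects carry predicted-vs-observed
plot data with ±1/±2/±3 percentage-point deviance band membership, and
serialise losslessly to JSON/CSV.

## The synthetic world: what it emulates, and what it does not

The generator builds strata with static livelihood labels, monthly
populations, and AR(1) predictor series (lag-1 correlation 0.7 by default)
with seasonal structure for climate variables, Poisson counts for conflict
and epidemic events, and log-scale price series. True prevalence per
binary case definition is the inverse-logit of a linear predictor on the
standardised 1–3-month lagged means of the configured variables plus a
livelihood offset; default intercepts put SAM-WFH near 3.5 %, GAM-WFH near
16 %, SAM-MUAC near 1.2 % and GAM-MUAC near 8 % — the neighbourhood of
median survey estimates reported from East-African surveillance. Block
missingness (contiguous 2–4 month runs, 10 % of cells by default) is
injected into the delivered panel only; the truth surface is computed from
the complete series.

Surveys draw cluster effects that are normal on the logit scale with
variance solved from the target intra-cluster correlation
(σ² = ICC·π²/3 / (1 − ICC); default ICC 0.03, a typical magnitude for
anthropometric cluster surveys — the real data's ICC is not published, so
this is an exposed placeholder). The cluster-level intercept is adjusted
by quadrature so the *marginal* prevalence equals the truth at any ICC;
without this, the logit-normal average would attenuate it. Child case
status is drawn per definition; WHZ and MUAC are then drawn from normal
distributions truncated to the region the status implies, so
dichotomising reproduces the drawn status exactly, and weight is
back-solved through the LMS reference so reanalysis recovers the drawn
z-scores. Oedema is a rare independent Bernoulli (0.5 %) that overrides
to SAM; the anthropometric category draw is conditioned on it so the
marginal prevalence still equals the truth. By default 30 % of eligible
stratum-months receive a survey (sparse coverage of the kind seen when
~29 % of districts can be surveyed), eligibility starting after the
6-month lag horizon so every surveyed month has a full feature history.

What passing tests on this world demonstrate: that the formulas are
implemented exactly (brute-force agreement at 10⁻¹²), that the fitting
machinery recovers known coefficients within sampling error, that the
interval constructions are calibrated under their own assumptions, and
that model search finds a generating model placed among the candidates.
What they do not demonstrate: performance on real data — the generator has
no measurement error, digit preference, survey-team effects, reporting
bias, reverse causation from humanitarian response, or spatial structure,
all of which degrade real-world predictive value.

## Numerical choices and experiment sizes

Calibration experiments fix their own conditions: the coefficient-recovery
and interval-coverage study uses 40 strata × 36 months, 30 × 20-child
surveys at 65 % of eligible stratum-months, with ICC 0 — the correctly
specified condition for the binomial sampling layer in the interval; the
cluster-robust machinery under ICC > 0 is validated separately on the
survey estimator. The model-search study uses 12 strata × 30 months, 144
surveys of 600 children, and 31 candidate subsets of 4 true + 1 noise
predictor, 50 seeded replicates. RF coverage uses 20 replicates of
200-row tables with 2000 trees, judged by a 3-sigma band on the mean of
per-replicate coverages (test points within a replicate share one forest,
so the pooled binomial band would be anti-conservative). Determinism is
enforced by deriving every stage seed from one master seed and running
ranger single-threaded.

## Limitations

Nearest-market relationships are supplied by configuration (stratum order
by default), not computed from coordinates; there is no geospatial layer.
Mixed models are deliberately out of scope — random stratum effects are
inestimable precisely in the unsurveyed strata one most wants to predict.
Regularised selection (lasso) and boosted trees are not implemented. The
chained imputer assumes approximately linear-gaussian relations between
panel variables; heavily skewed series should be transformed first.
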
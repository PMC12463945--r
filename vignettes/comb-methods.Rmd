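---
title: "Methods: psychometrics, structural modeling and rule mining for COM-B surveys"
author: "combmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometrics, structural modeling and rule mining for COM-B surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combmine)
```

# The analysis problem

COM-B studies of occupational health behavior measure four modules —
Capability, Opportunity, Motivation and Behavior — with multi-item Likert
scales: each first-order *domain* (e.g. behavioral regulation, policies and
norms) is a reflective latent variable measured by three to five 5-point
items, and the outcome is a set of single-item risk-coping behaviors. The
standard analysis has three stages, all implemented here:

1. **Scale evaluation.** Item screening by corrected item-total correlation,
   principal-component factor analysis with varimax rotation on the first
   half of the sample, retention rules on loadings and cross-loadings, and
   reliability/validity statistics (Cronbach's alpha, composite reliability
   CR, average variance extracted AVE, Fornell–Larcker discriminant
   validity).
2. **Structural modeling.** Maximum-likelihood covariance-structure
   estimation of a second-order factor model (domains nested in modules)
   with structural regressions Motivation ~ Capability + Opportunity and
   Behavior ~ Motivation + Opportunity + Capability, the usual fit-index
   battery, and bootstrap mediation tests of the indirect paths through
   Motivation.
3. **Association-rule mining.** Domain mean scores discretized to
   High/Middle/Low, Apriori frequent-itemset mining over the resulting
   transactions, rule filtering by support/confidence/lift, partitioning by
   behavior consequent, top-10-lift strong rules per partition, and
   domain-frequency profiling.

Because raw survey data of this kind are rarely distributable, the package
ships a synthetic-data generator whose latent structure matches the model
the analysis assumes, so every stage is testable end to end.

# The synthetic-data generator

`generate_responses()` draws the exogenous module factors (Capability,
Opportunity) from a bivariate standard normal with correlation `exo_cor`,
propagates them through the standardized structural paths to Motivation and
Behavior with disturbance variances chosen so every module factor has unit
variance, emits domain factors (`second_order` loading times module factor
plus residual) and standardized item latents (`loading` times domain factor
plus noise), and cuts each item latent at four thresholds into the 1..5
response categories.

Default parameter choices, fixed once:

* **Structural paths** `(0.21, 0.18, 0.41, 0.26, -0.04)` for C→M, O→M, M→B,
  O→B, C→B — the reference standardized solution of the published
  construction-worker study this design emulates, used as simulation ground
  truth for the recovery tests.
* **First-order loadings** for the Capability and Motivation items are the
  published standardized loadings (0.70–0.86). Per-item loadings for the
  Opportunity items and the behavior items are not published; they are fixed
  at 0.80 and 0.75 — typical magnitudes for retained reflective indicators
  in this literature.
* **Capability–Opportunity correlation** is not published; it is fixed at
  0.5, a moderate positive association consistent with the reported pattern
  of inter-module relations.
* **Thresholds** `(-1.5, -0.5, 0.5, 1.5)` on the standardized item latent.
  These are symmetric, so category 1 and 5 (and 2 and 4) are equally
  frequent and the mean response sits near 3, matching the reported
  observation that mean scores cluster around 3. Likert generation is a
  thresholded latent normal with the same thresholds for every item — a
  graded-response-style mechanism, the simplest one compatible with treating
  the items as reflective continuous indicators downstream.
* **Missingness** is off by default; an optional MCAR mask with a stated
  rate is available.

What the generator does *not* emulate: response styles (acquiescence,
extreme responding), item-specific thresholds, floor/ceiling asymmetries,
and clustering by site or crew. Tests passing on these data therefore
validate the computational pipeline and its statistical properties under the
assumed model, not robustness to those real-data features.

One consequence of thresholding worth knowing: treating 5-category responses
as continuous attenuates inter-item covariances by roughly 6% at these
thresholds, so standardized *loadings* estimated from Likert data sit
slightly below their latent ground truth. Standardized *structural paths*
are ratios of latent covariances and are essentially unaffected, which is
why the recovery tests target the paths.

# Psychometric stage

All variances and correlations use the sample (n−1) denominator.

* `corrected_item_total()` correlates each item with the sum of the other
  items of its subscale. Items below 0.5 are flagged first.
* `efa_pca_varimax()` performs principal-component factor analysis on the
  item correlation matrix, retains components with eigenvalue > 1, and
  rotates with varimax. The rotation is the classical pairwise-sweep
  algorithm with Kaiser normalization, run to a criterion improvement below
  1e-15 (machine optimum; with looser tolerances agreement with the
  reference implementation in `stats::varimax` degrades to ~1e-6 in the
  loadings). The sign convention makes each factor's largest-magnitude
  loading positive.
* `apply_item_retention_rules()` applies, in a deterministic order,
  item-total → primary loading (> 0.5 required) → cross-loading (> 0.5
  eliminates) → orphan-factor (factors left with fewer than three items are
  dissolved). Each eliminated item carries exactly one primary reason: the
  first rule that fired. Elimination is single-pass by default: the analysis
  workflow this mirrors re-ran the factor analysis once after elimination,
  and a fixed-point iteration can be had by calling the EFA and the rules
  again on the reduced item set.
* `kmo()` computes anti-image partial correlations from the inverse
  correlation matrix; `bartlett_sphericity()` uses
  \(\chi^2 = -(n-1-(2p+5)/6)\ln|R|\) on \(p(p-1)/2\) degrees of freedom.
* `ave()` is the mean squared standardized loading; `composite_reliability()`
  is \((\Sigma\lambda)^2 / ((\Sigma\lambda)^2 + \Sigma(1-\lambda^2))\).
  Fornell–Larcker passes for a factor when \(\sqrt{AVE}\) strictly exceeds
  every absolute inter-factor correlation — equality fails.
* `split_half()` defaults to an ordered first-half/second-half split
  (mirroring the common EFA/CFA split description); a seeded random split is
  available.

Missing responses are handled by listwise deletion within each computation.

# Structural equation modeling

Models are specified in a small text DSL (`factor`, `second`, `path`,
`cov` statements) and compiled to RAM form: with directed-path matrix
\(A\) (loadings and regressions) and symmetric matrix \(S\) (variances,
disturbances, covariances) over observed and latent variables,
\(\Sigma(\theta) = F(I-A)^{-1} S (I-A)^{-\top} F^\top\). `fit_ml()`
minimizes the ML discrepancy
\(F_{ML} = \ln|\Sigma| + \mathrm{tr}(S_{samp}\Sigma^{-1}) - \ln|S_{samp}| - p\)
with `nlminb` and the analytic gradient
\(\mathrm{tr}[(\Sigma^{-1}-\Sigma^{-1}S_{samp}\Sigma^{-1})\,d\Sigma]\),
which keeps a full 59-indicator COM-B fit under a third of a second and a
warm-started bootstrap refit under ~60 ms.

Numerical choices:

* **Identification.** Exogenous latent variances are fixed at 1 with all
  loadings free; endogenous latents (regression outcomes and first-order
  factors under a second-order factor) are scaled by fixing their first
  loading to 1 with a free disturbance. AMOS-style software fixes the first
  loading throughout; the standardized solution — what gets reported — is
  invariant to this choice, and the package always derives it from the
  model-implied variances.
* **Starts.** The default start sets loadings near 0.7 (scaled by the median
  observed SD) and paths near 0.1; `n_starts = 5` jittered restarts guard
  against local minima (jitter drawn under a local seed that does not
  disturb the caller's RNG stream). Bootstrap refits warm-start from the
  full-sample estimate with a single start.
* **Convergence** is `rel.tol = 1e-10` on the objective; a fit whose best
  discrepancy is still at the failure ceiling raises an error carrying the
  gradient norm. Negative residual-variance estimates (Heywood cases) are
  not constrained away; they are flagged on the returned object.
* **chi-squared** uses \((n-1)F_{ML}\), which also enters the RMSEA
  denominator. The baseline for incremental indices is the independence
  model, whose ML solution is available in closed form
  (\(F_b = \Sigma\ln s_{ii} - \ln|S|\)). For a saturated model (df = 0)
  AGFI, RMSEA and TLI are reported as missing with a note rather than
  fabricated.
* **SRMR** averages squared standardized residuals over the lower triangle
  including the diagonal.

`bootstrap_mediation()` resamples respondents with replacement, refits on
each resample covariance, and forms the indirect effect per replicate as the
product of the two standardized path estimates. Intervals are percentile
(2.5/97.5 empirical quantiles) and bias-corrected
(\(z_0 = \Phi^{-1}(\text{prop. of replicates} < \hat\theta)\), bounds at
\(\Phi(2z_0 \pm 1.96)\)); p-values are two-sided bootstrap percentile
p-values, since the inferential claims in this design rest on bootstrap
intervals rather than normal-theory standard errors; the reported standard
error is the bootstrap SD. Replicates with a non-positive-definite resample
covariance or a failed refit are dropped and counted; more than 10% dropped
is an error. Classification: *full* mediation when the bias-corrected
indirect interval excludes zero and the direct interval does not, *partial*
when both exclude zero, *none* otherwise.

A note on modification indices: common SEM software suggests respecification
through Lagrange-multiplier modification indices. The package instead
provides `item_misfit_ranking()` — exact leave-one-item-out refitting ranked
by the drop in \(F_{ML}\) — which reproduces "remove the worst item"
decisions without the quadratic approximation; no M.I. approximation is
provided.

# Discretization and rule mining

`categorize_score()` maps a domain mean score \(s \in [1,5]\) to L
(\(s < 3\)), M (\(3 \le s < 4\)) or H (\(s \ge 4\)); both boundaries are
half-open exactly as stated, so 3.0 is M and 4.0 is H. Scores are computed
per respondent on retained items (configurable to all items — whether the
original analysis used retained or all items is not stated, so the
post-screening set is the default as it matches the analysis sequence) and
categorized once, before any partitioning. Respondents missing any item of
a domain are dropped from the transaction table and enumerated, so
transactions are in bijection with retained respondents.

`apriori_frequent_itemsets()` is a from-scratch level-wise Apriori: each
frequent itemset carries its transaction-indicator vector, so a candidate's
support is a single vectorized AND; joining two frequent (k−1)-sets sharing
their k−2 prefix generates every frequent k-set exactly once. Support is
always a proportion of *all* transactions.

`generate_rules()` emits X → Y for every frequent itemset containing exactly
one behavior element Y, with confidence \(P(X,Y)/P(X)\) and lift
\(P(Y|X)/P(Y)\). Thresholds: support and confidence are minima (≥), lift is
strict (>), following the verbatim operator wording of the design this
mirrors ("minimum support/confidence", "lift > 2"). Antecedents are
restricted to non-behavior domains by default (the reported analysis surface
predicts one behavior from the 15 domains); a flag allows unrestricted
mining. The default antecedent size is unlimited — the vocabulary is at most
23 × 3 elements — with an optional cap.

`partition_and_filter()` groups rules into at most 16 partitions (8
behaviors × {H, L}; M-consequent rules are dropped first) and removes rules
whose antecedent contains any M-level element, unless that element's domain
is listed in the partition's exception set. The exception mechanism exists
because a partition can end up with very few rules; which single domain's M
level to exempt is a per-analysis judgment, so it is an explicit user-supplied
list rather than an automatic pick. `top_strong_rules()` ranks by lift with
the deterministic tie-break (confidence, then support, then antecedent
lexicographic) and keeps the top 10; ties at the boundary are flagged.
`domain_frequency()` counts domain appearances over the strong rules and
flags domains at the ≥ 5 threshold.

# What the tests establish, and on what problem sizes

The test suite validates each statistic against an independent route:
exhaustive enumeration for Apriori and rule generation (50 random tables of
up to 12 elements and 200 transactions), `stats::varimax` and
`stats::factanal` for rotation and ML estimation, regression-residual
partial correlations for KMO, closed forms for alpha, Bartlett, AVE/CR, the
triad rule for a just-identified factor model, and a 200,000-draw Monte
Carlo for the RAM covariance algebra.

The simulation studies use the study-scale sample size n = 484 with the
reference path values as ground truth: 20 replicates with B = 500 bootstrap
resamples for path-recovery coverage and mediation classification, and 50
replicates (n = 300, B = 500) for the null-indirect coverage check on a
compact three-factor mediation model. B = 500 rather than the 5,000 of a
full analysis keeps each replicate's interval estimate light while leaving
the coverage assessment meaningful; the full pipeline default remains
B = 5000.

# Known limitations

* Pearson correlations on 5-point items (no polychoric option); the
  attenuation noted above is the visible consequence.
* Orthogonal rotation only; no oblique rotations, parallel analysis or
  omega coefficients.
* ML estimation only; no robust or ordinal (WLSMV-style) estimators and no
  multi-group invariance machinery.
* Rule mining implements exactly the support/confidence/lift filter set with
  middle-level elimination; no FP-growth, no redundancy pruning beyond those
  filters, and no statistical correction of rule significance.
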
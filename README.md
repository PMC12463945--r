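# combmine

Analysis toolkit for **COM-B questionnaire studies of occupational health
risk-coping behavior**: psychometric scale evaluation, second-order
structural equation modeling with bootstrap mediation, and association-rule
mining over discretized domain scores — plus a latent-factor Likert
simulator so the whole pipeline can be exercised and tested without access
to raw survey data.

It is written for researchers who measure the COM-B modules (Capability,
Opportunity, Motivation, Behavior) with multi-item 5-point Likert scales —
here 15 behavior-change domains and 8 single-item risk-coping behaviors —
and need the standard three-stage analysis in one reproducible place.

## What it computes

**Scale evaluation.** Corrected item-total correlations,
principal-component factor analysis with varimax rotation (eigenvalue > 1
retention), KMO and Bartlett sphericity, item retention rules (loading
> 0.5, cross-loading > 0.5 eliminates, factors with < 3 items dissolve),
Cronbach's α, and for standardized loadings λ of a construct with k items:

    AVE = Σλ² / k            CR = (Σλ)² / ((Σλ)² + Σ(1 − λ²))

with Fornell–Larcker discriminant validity (√AVE must strictly exceed every
inter-factor correlation).

**Structural modeling.** RAM-form maximum-likelihood covariance-structure
estimation, minimizing F_ML = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p with an
analytic gradient; second-order factors (domains nested in modules);
fit indices χ²/df, GFI, AGFI, RMSEA, SRMR, NFI, TLI, CFI; mediation via
respondent bootstrap with percentile and bias-corrected 95% intervals on
the standardized indirect effect a·b.

**Rule mining.** Domain mean scores cut to L/M/H (score < 3 → L,
3 ≤ score < 4 → M, score ≥ 4 → H), from-scratch Apriori over the resulting
transactions, rules X → behavior with Support = P(X,Y),
Confidence = P(X,Y)/P(X), Lift = P(Y|X)/P(Y) filtered at support ≥ 5%,
confidence ≥ 50%, lift > 2 (strict), partitioned by behavior × {H, L} with
middle-level elimination, top-10-lift strong rules per partition, and
domain-frequency profiling (flag at ≥ 5 of 10).

## Worked example

```r
library(combmine)

spec <- default_instrument()        # 15 domains, 51 items, 8 behaviors
d <- generate_responses(ground_truth(spec), n = 484, seed = 1)

reliability_validity(d, spec, "Capability")
#> Reliability and validity: Capability module
#>  domain k alpha    cr   ave sqrt_ave
#>      BR 3 0.815 0.788 0.554    0.744
#>      DM 3 0.793 0.777 0.539    0.734
#>      KS 3 0.805 0.763 0.519    0.720
#>
#> Domain-score correlations (discriminant validity by Fornell-Larcker):
#>       BR    DM    KS
#> BR 1.000 0.650 0.595
#> DM 0.650 1.000 0.609
#> KS 0.595 0.609 1.000
#>   discriminant validity: pass for all domains
```

Each domain clears the usual reliability bars (α and CR near or above 0.7,
AVE above 0.5), and √AVE exceeds the between-domain correlations, so the
three Capability domains are internally consistent and distinguishable.

```r
fit <- sem_fit(comb_model(spec), d)
fit
#> SEM fit: 59 observed, 139 free parameters, n = 484
#>   F_ML = 3.724858, chi2 = 1799.106, df = 1631
#>   standardized structural paths:
#>     Motivation ~ Capability    0.257
#>     Motivation ~ Opportunity   0.165
#>     Behavior ~ Motivation    0.407
#>     Behavior ~ Opportunity   0.287
#>     Behavior ~ Capability   -0.092
fit_indices(fit)
#>     chi2       df  chi2_df      GFI     AGFI    RMSEA     SRMR      NFI
#> 1799.106 1631.000    1.103    0.892    0.883    0.015    0.036    0.890
#>      TLI      CFI
#>    0.988    0.989
```

The standardized paths land near the simulator's ground truth
(0.21, 0.18, 0.41, 0.26, −0.04): Motivation is the strongest direct
determinant of Behavior, the Capability→Behavior direct path is
indistinguishable from zero, and the fit indices sit in the conventional
acceptable region (χ²/df ≈ 1.1, RMSEA ≈ 0.015, SRMR ≈ 0.036, CFI ≈ 0.99).
`bootstrap_mediation(comb_model(spec), d, "Capability", "Motivation",
"Behavior", B = 5000, seed = 1)` then tests the indirect path and classifies
the mediation (full / partial / none) from the bias-corrected intervals.

The rule-mining stage follows the same data:

```r
tt <- build_transactions(d, spec)
parts <- top_strong_rules(partition_and_filter(mine_rules(tt)))
domain_frequency(parts, threshold = 5)
```

An end-to-end run (simulate → psychometrics → SEM → categorize → mine →
report) with all thresholds at their defaults is
`run_pipeline(pipeline_config("out/", n = 484, seed = 1))`; it writes CSV/
JSON stage outputs, a Markdown report and a manifest with file hashes. A
thin command-line wrapper lives in `inst/scripts/comb-pipeline.R`.

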
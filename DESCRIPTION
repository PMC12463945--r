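Package: combmine
Title: COM-B Occupational Health Behavior Analysis with Psychometrics, SEM
    and Association Rule Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for COM-B (Capability, Opportunity,
    Motivation, Behavior) questionnaire studies of occupational health
    risk-coping behavior. Provides a latent-factor Likert response simulator,
    psychometric scale evaluation (item screening, principal-component factor
    analysis with varimax rotation, KMO and Bartlett tests, Cronbach's alpha,
    composite reliability, average variance extracted, Fornell-Larcker
    discriminant validity), covariance-structure maximum-likelihood estimation
    of first- and second-order factor models with the standard fit-index
    battery, bias-corrected bootstrap mediation tests, High/Middle/Low score
    discretization, and from-scratch Apriori association-rule mining with
    support/confidence/lift filtering, behavior-partitioned strong-rule
    extraction and domain-frequency profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
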
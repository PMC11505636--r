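Package: icrscore
Title: Index of Caries Risk Scoring and Method-Comparison Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Index of Caries Risk (ICR), a pediatric caries
    risk assessment instrument built from eight ordinal questionnaire and
    clinical items, together with the analytics needed to compare it against
    the Cariogram tool: the risk-complement transform of the Cariogram
    "chance of avoiding caries" percentage, categorical risk binning for both
    instruments, descriptive summaries, rounded frequency tables,
    cross-tabulation with marginal reconciliation, Pearson correlation with
    Fisher-z confidence intervals, weighted and unweighted Cohen's kappa, and
    Fisher-z sample-size calculation for correlation studies. A seeded
    one-factor Gaussian-copula simulator generates synthetic pediatric
    cohorts with configurable item marginals, latent-risk-driven inter-item
    correlation, a coupled Cariogram value, and a dropout process, so the
    full comparative analysis can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    caret
Config/testthat/edition: 3
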
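Package: symfactor
Title: Genetic Factor Models of Depression Symptoms Across Clinical and
    Community Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the genetic structure of major depression
    symptoms from GWAS summary statistics. Implements inverse-variance
    meta-analysis with effective-sample-size bookkeeping, LD-score regression
    for SNP heritability and genetic covariance with a block jackknife and
    liability-scale conversion under clinical and community ascertainment,
    confirmatory genetic factor models fit by diagonally weighted least
    squares (including measurement models for gated symptom surveys),
    per-SNP common- versus independent-pathway heterogeneity tests (Q_SNP),
    and genetic single and multiple regression against external traits with
    Benjamini-Yekutieli FDR control. A multi-cohort simulator generates
    symptom GWAS with known factor structure, liability-threshold
    ascertainment, and gating (skip-pattern) missingness for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
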
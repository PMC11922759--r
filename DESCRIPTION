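Package: expowas
Title: Exposome-Wide Survival Screening and Environment-Versus-Genetics
    Variance Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for exposome-wide association studies (XWAS)
    of mortality and aging on large prospective cohorts: multiple imputation
    by chained random forests with predictive mean matching and Rubin's-rule
    pooling; serial stratified left-truncated Cox screening with
    discovery/replication false discovery rate control; reverse-causation,
    residual-confounding (PheWAS) and proteomic-age concordance filters;
    heterogeneous (Pearson/polyserial/polychoric) correlation clustering
    with within-cluster multivariable pruning; outcome panels for incident
    disease, aging biomarkers and metabolic risk factors; and sequential
    multivariable models partitioning outcome variation between age and sex,
    polygenic risk scores and the exposome via explained-randomness R-squared
    and Wald chi-squared importance, with holdout validation. Includes a
    synthetic cohort generator with planted causal structure so every stage
    is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
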
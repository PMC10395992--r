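Package: mcdtpi
Title: Motor-Cognitive Dual-Task Pooled Indices for Cognitive Impairment Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motor-cognitive dual-task (MCDT) assessments
    of older adults. Computes classical and commitment-weighted dual-task costs
    from wearable-sensor motor feature tables, builds correlation-screened
    pooled indices (PIs) that summarise dual-task degradation per exercise,
    and evaluates leave-one-out cross-validated logistic models that
    discriminate cognitively normal adults (CNA), subjective cognitive
    impairment (SCI), and mild cognitive impairment (MCI). Includes a
    synthetic-cohort generator emulating the statistical structure of a
    three-group clinical study, nonparametric group comparisons
    (Kruskal-Wallis, Mann-Whitney with Bonferroni correction, chi-squared),
    and a one-call pipeline with reproducible, provenance-stamped outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nnet,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
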
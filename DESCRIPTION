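Package: mcodeflow
Title: Synthetic Oncology EHR Extracts, mCODE FHIR Genomics Profiles, and
    Cohort Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pilot toolkit for oncology EHR interoperability.
    Generates synthetic Epic-Clarity-style tabular extracts (patients,
    Phecode-coded cancer diagnoses, genomic test reports, gene-variant
    observations, specimens), transforms them through a three-step
    extract-transform-load pipeline into validated mCODE FHIR R4 genomics
    profiles with data-absent-reason placeholders and anchored extensions,
    stores them in an entity-attribute-value profile store with FHIR-style
    paginated search (1,000-profile page limit), and computes cohort
    statistics: top-N gene and Phecode distributions, filtered deidentified
    summary tables, and a Bayes conditional cancer-incidence calculator over
    a TCGA-style 33-label cancer set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    parallel,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
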
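Package: heteromiR
Title: Heterogeneity-Aware MicroRNA Biomarker Discovery for Multifocal Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover and evaluate prognostic microRNA biomarkers in
    cohorts where each patient may contribute several tumor samples with
    heterogeneous expression profiles (multifocal hepatocellular carcinoma
    being the motivating setting). The pipeline clusters samples into two
    expression subgroups, resolves within-patient heterogeneity by grouping
    patients as pure or mixed with respect to the sample clusters, builds a
    patient-disjoint training set, ranks features by mutual information
    between quartile-discretized expression and prognosis class, classifies
    samples and patients from the selected biomarker panel, and evaluates
    strata by Kaplan-Meier curves, log-rank tests and Cox proportional
    hazards models (including strata combined with the Milan transplantation
    criteria). A synthetic multifocal-cohort generator with known ground
    truth supports end-to-end testing, and a patient-level min/max
    summarization baseline is provided for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
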
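Package: comorbinet
Title: Comorbidity Patterns in Periodontitis Cohorts: Clustering and
    Hypergraph Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing comorbidity and multimorbidity patterns in
    periodontitis patient cohorts. Provides a calibrated synthetic-cohort
    generator (three-class mixture over 26 binary disease indicators with
    class-conditional demographics and periodontal metrics), descriptive
    prevalence accounting, two-step clustering of patients under the
    log-likelihood (entropy) distance with BIC-guided selection of the
    cluster count, covariate-adjusted logistic comparison of disease
    prevalence between clusters, and a hypergraph co-occurrence network
    over multimorbid patients with principal-eigenvector disease
    centrality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
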
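Package: comorbid
Title: Comorbidity Pattern Mining from Electronic Medical Records
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mines comorbidity patterns of older lung-cancer patients from
    ICD-10 coded electronic medical records. Provides cohort ingestion and
    eligibility filtering, Pareto rank-frequency selection of predominant
    morbidities, from-scratch Apriori association-rule mining with
    support/confidence/lift metrics and same-itemset deduplication, weighted
    disease co-occurrence networks with modularity community detection, rule
    heatmaps, and a synthetic EMR cohort generator with planted conditional
    dependencies whose rule metrics are analytically computable, so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
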
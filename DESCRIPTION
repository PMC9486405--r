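Package: hnsubtype
Title: Gene-Expression Subtyping and Prognostic Analysis for HPV-Negative
    Head and Neck Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular subtyping of head and neck squamous cell
    carcinoma from bulk RNA-seq expression and for downstream prognostic
    analysis. Implements a balanced nearest-centroid subtype classifier
    (ClaNC-style per-class t-statistics with an equal high/low gene split per
    subtype, silhouette call strength, cross-validated signature-size
    selection), an HPV status caller from per-type viral read counts, cohort
    descriptive statistics and association tests, and Kaplan-Meier /
    log-rank / Cox survival analysis censored at a fixed horizon. A
    synthetic-cohort generator with known subtype structure, nodal
    positivity and survival hazards makes the full pipeline testable without
    access to controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
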
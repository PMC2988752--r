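Package: zmeta
Title: Multilevel Signed Z-Score Meta-Analysis for Candidate Gene
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combines per-study differential-expression summaries
    (p-values with up/down direction) into signed standard-normal
    deviates and aggregates them with Stouffer's method across studies,
    balances average absolute Z across cancer types, contrasts
    bone-metastasizing against non-bone-metastasizing cancers, and nests
    two further levels of averaging with prostate normal-vs-localized and
    localized-vs-metastatic comparisons to rank candidate genes for
    prostate cancer progression. Includes gene-set relative-Z enrichment
    and correlation-based validation statistics, interaction-network hub
    selection by degree and connectivity ratio, and a seeded synthetic
    multi-study generator with planted effects and hubs so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
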
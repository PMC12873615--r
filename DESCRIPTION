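Package: overlapCCA
Title: Corrected Covered Area Overlap Assessment for Overviews of Systematic Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies primary-study overlap in overviews of systematic
    reviews with the corrected covered area (CCA) statistic. Builds evidence
    (citation) matrices from an overview dataset as SummarizedExperiment-based
    objects, applies the four matrix-construction assumptions (level of
    analysis, scope, publication threads, structural missingness) to produce
    any of sixteen construction scenarios, computes overall and pairwise CCA
    with structural-zero denominator adjustment, classifies overlap against
    the published interpretation bands, and sweeps all scenarios to measure
    how sensitive the CCA is to matrix-construction choices. Includes a
    seeded synthetic-overview generator with tunable overlap, publication
    threads, outdated-review structure and outcome labels, so every pipeline
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
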
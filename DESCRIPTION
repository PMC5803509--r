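Package: connectopls
Title: Imaging Transcriptomics of Structural Connectome Atrophy via Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links regional white-matter connectivity loss in grouped
    structural connectomes to regional gene expression. Connectomes are scored
    per cortical region and connection class (corticostriatal,
    interhemispheric, intrahemispheric) as control-referenced atrophy and
    rate-of-atrophy measures; partial least squares regression then extracts
    gene-weight and region-score patterns with maximal covariance between
    expression and loss. Downstream statistics include exact
    minimum-hypergeometric ranked gene-set enrichment, mean-weight permutation
    tests, hypergeometric overlap tests, and donor-resampling and noise
    robustness checks. A synthetic-data module generates atlases, cohorts,
    donor-level expression, gene sets and fold-change tables with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
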
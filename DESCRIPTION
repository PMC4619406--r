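Package: dyncoex
Title: Dynamic Gene Co-Expression Networks: Module Evolution and Strength Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-timestamp weighted gene co-expression networks from
    longitudinal expression data by Pearson-correlation thresholding, detects
    overlapping functional modules per timestamp with non-negative matrix
    factorization, classifies the five module evolutionary events (form,
    dissolve, continue, split, merge) between consecutive timestamps under an
    overlap threshold, and tracks each module's internal-versus-external
    interaction strength over time with temporal smoothing, cross-module
    normalization and progression-pattern classification. Includes a synthetic
    longitudinal-cohort generator with planted, evolving co-expression modules
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
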
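Package: protopanel
Title: Batch-Effect-Aware Biomarker Panel Selection for Protein Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated discovery workflow for autoantibody profiling studies on
    high-density protein microarrays. Reads GenePix results (gpr) files in batch,
    assembles and normalizes protein-level intensity matrices, computes the
    subgroup-sensitive minimum M statistic (hypergeometric exceedance score) for
    two-group comparisons, selects candidate biomarker panels by a hybrid scheme
    (score voting across clinical and production-lot comparisons, manual voting,
    preselection rules, and an evolutionary-algorithm wrapper around a random
    forest), and validates panels on repeated stratified train/test splits.
    Includes a synthetic-study generator with planted markers and lot effects so
    every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    limma,
    randomForest,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
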
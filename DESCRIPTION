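Package: devvar
Title: Differential Expression-Variability Screening for Age-Grouped
    Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens expression studies for genes whose inter-individual
    variance differs between age groups, as in developmental brain
    transcriptomics where childhood samples show greater expression
    variability than adult samples. Implements the full pipeline:
    detection-p filtering, global offset and log2 transform, quantile
    normalization, technical-replicate averaging and sex adjustment; a
    one-sided variance-ratio F-test per probe with Benjamini-Hochberg and
    Storey positive false discovery rate control; a paired signed-rank
    summary and proportion-greater statistic; quadratic age-trajectory
    exclusion via nested-model F-tests; hypergeometric over-representation
    against dual reference universes; cross-dataset replication statistics
    (expected overlap, Fisher exact 2x2, cross-platform correlation); and a
    synthetic-data generator with ground-truth labels for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
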
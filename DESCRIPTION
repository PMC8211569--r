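Package: coexscreen
Title: Pan-Cohort Screening of Differential Expression and Gene-Pair
    Correlation Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for screening paired normal/cancer expression
    cohorts for genes with consistent expression trends, differentially
    expressed genes (normalized log2 fold-change with a two-group Poisson
    likelihood-ratio test), and gene pairs whose Pearson correlation
    changes consistently between conditions across all cohorts, classified
    into six sign/magnitude transition categories.  Includes a BioGRID
    interaction-file parser with direct-neighborhood subnetwork
    extraction, a synthetic cohort generator with planted fold-changes and
    planted correlation decoupling for end-to-end validation, correlation
    dot-matrix plots, and tidy accessors for all result types.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
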
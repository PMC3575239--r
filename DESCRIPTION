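Package: nimtools
Title: Neutral Indel Model Constraint Estimation and Comparative Genome QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the amount of selectively constrained (indel-purified)
    sequence shared by a species pair from a pairwise whole-genome alignment
    using the Neutral Indel Model: inter-gap segment lengths are histogrammed
    within equally populated G+C bins, a geometric neutral expectation is
    extrapolated from short segments, and the excess of long segments is
    converted to lower and upper bounds on constrained bases via K and 2K
    corrections. Also provides a two-branch indel/substitution alignment
    simulator with exact truth ledgers, draft-assembly quality estimators
    (coverage-based genome size, euchromatic completeness, splice-site
    substitution audit, three-way indel error bound, aligned fractions,
    gene-set completeness), the stringent codon-alignment filtering cascade
    used upstream of branch-site positive-selection tests, and site-level
    Gene Ontology enrichment with hypergeometric tests and Bonferroni
    correction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
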
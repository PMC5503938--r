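Package: snofrag
Title: Detection and Quantification of snoRNA-Derived RNAs from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and quantifying snoRNA-derived RNAs
    (sdRNAs) in adapter-trimmed small RNA sequencing libraries. Reads are
    placed on a snoRNA reference catalog by perfect-match alignment under
    configurable length windows, per-snoRNA excision profiles distinguish
    fixed-position processing from degradation, and expression is quantified
    in counts per million (CPM) with threshold-based expression flags,
    differential-overexpression tiers, and processing-preference ratios.
    A cohort analyzer computes per-subtype expression prevalence of a query
    sdRNA across labeled sample collections, a local-alignment module screens
    snoRNA catalogs against miRNA hairpin catalogs for sequence relatedness,
    and a synthetic-data generator produces catalogs, libraries, and cohorts
    with known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
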
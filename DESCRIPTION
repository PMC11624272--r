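Package: stagloop
Title: STAG2-Dependent Enhancer-Promoter Contact Analysis for Ewing Sarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how loss of the cohesin subunit STAG2 rewires
    enhancer-promoter communication in Ewing sarcoma. Includes a scanner for
    chained GGAA microsatellite runs (the EWS::FLI1 neoenhancer substrate),
    spike-in (occupancy ratio) calibration of ChIP-seq signal, promoter
    capture Hi-C loop filtering with common/gained/lost classification,
    bait-row and distance-decay (observed-over-expected) normalization of
    sparse binned contact matrices with anchor-centered pileups, assignment
    of genes to promoter/distal enhancer-contact classes, and a STAG2-loss
    expression-signature patient classifier with Kaplan-Meier and Cox
    proportional-hazards survival comparison. A synthetic-data module
    generates every input with planted ground truth so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
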
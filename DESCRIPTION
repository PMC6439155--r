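Package: masplan
Title: Population Sizing and Marker Evaluation for Marker-Assisted
    Selection in Breeding Programs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative planning tools for marker-assisted selection
    (MAS) in crop breeding programs using rapid generation advance.
    Provides exact Mendelian segregation ratios for selfing series,
    backcross and doubled-haploid populations; exact binomial
    minimal-population-size calculators for forward breeding,
    recombinant selection against linkage drag, and line augmentation;
    two-stage F2-enrichment planning; Monte-Carlo validation of every
    analytic ratio and failure probability; grading of candidate
    diagnostic markers (false-positive rate, false-negative rate, call
    rate, per-cross success prediction) against germplasm panels; QTL
    effect-size assessment and deployment-strategy recommendation; and a
    command-line interface with CSV panel and minimal VCF input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
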
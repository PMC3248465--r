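Package: epiclone
Title: Clone-Based Bisulfite Amplicon Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of clone-based bisulfite PCR sequencing of promoter
    amplicons, as used to study temperature-dependent sex determination via
    CpG methylation of the gonadal aromatase (cyp19a) promoter in fish.
    Provides methylation calling at declared CpG loci with per-clone
    bisulfite conversion-efficiency QC, epiallele (methylation pattern)
    frequency analysis with contingency tests, hierarchical AMOVA on
    methylation haplotypes with permutation-based Phi/Fst significance,
    group statistics on arcsine square-root transformed per-fish methylation
    means including a confidence-interval based sex-classification
    threshold, qPCR delta-delta-Ct relative quantification with two-cluster
    presumptive sexing, and a seedable synthetic-data generator emulating
    the study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
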
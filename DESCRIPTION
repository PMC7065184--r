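Package: mcec
Title: Molecular Classification and Genomic Analysis of Multiple-Classifier Endometrial Carcinomas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the surrogate-marker molecular classification of
    endometrial carcinoma (POLEmut, MMRd, p53abn, NSMP) with explicit
    resolution rules for tumours carrying more than one classifying feature,
    96-channel trinucleotide mutational spectra with a cosine-based sample
    distance, fraction of genome altered from copy-number segments, combined
    hierarchical clustering with reference-group assignment, contingency
    statistics on TP53 variant features, and Kaplan-Meier / log-rank survival
    comparison. Ships a seeded synthetic cohort generator emulating the four
    TCGA-like subtypes so the whole pipeline is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
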
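Package: capturekit
Title: Design and Analysis of Paired-Nickase Clonal Barcoding Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for CRISPR nickase paired-gRNA clonal barcoding
    (lineage tracing with capturable barcodes). Designs stop-codon-free,
    frame-safe guide target sites and assembles combinatorial barcode
    cassette libraries; extracts and counts barcodes from amplicon
    sequencing reads by fixed-flank motif matching; calls enriched clones
    with a single-replicate gamma-Poisson posterior log2 fold-change
    statistic and evaluates a binomial preexistence model of resistance
    origin; classifies editing outcomes and reporter states from aligned
    amplicons; ranks candidate resistance variants with a multi-evidence
    priority score; and simulates barcoded clonal evolution under drug
    selection (preexisting and persister-derived acquired resistance) to
    generate fully synthetic test data with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
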
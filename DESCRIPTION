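Package: hicstress
Title: Hi-C Chromatin Interaction Calling and Stress-Condition Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of Hi-C read pairs for plant chromatin
    interactomes under stress conditions: restriction-fragment-aware removal
    of uninformative read pairs, distance-decay expected-count modelling with
    hill-climbing inference of per-bin totals, normalized and Pearson
    correlation contact matrices, cumulative-binomial calling of significant
    interactions at fine resolution, cross-condition interaction overlap and
    expression dynamics, epigenetic-state preference testing with randomized
    control interactions, GWAS-SNP depletion analysis, and motif-region
    sequence export. Includes a synthetic-data generator with known ground
    truth (planted enriched locus pairs, per-bin biases, SNP-depleted
    regions, expression effect genes) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
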
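Package: dipscan
Title: Domain Insertion Profiling: Permissibility Scoring, Differential
    Analysis and Functional Flow-Cytometry Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for domain insertion profiling by sequencing
    (DIP-seq) of a membrane protein coding sequence. Calls transposon-mediated
    insertion sites (nucleotide position, orientation, reading frame and
    productive status) from junction reads, converts sorted-pool read counts
    into per-residue permissibility enrichment scores with replicate means,
    z-scores and binarization, compares permissibility across inserted
    domains (correlation matrices, Hamming and Euclidean differential-site
    metrics, moving-average region calling, rank-sum tests), fits
    depth-limited decision-tree models predicting permissibility from protein
    properties with cross-validated ROC reporting and feature withholding,
    and implements flow-cytometry statistics for resting-membrane-potential
    assays (sequential gating, a lower-50 percent wild-type gate, chi-squared
    light/dark dissimilarity with photobleaching normalization, and
    many-to-one tests). A synthetic-data module generates every input with
    known ground truth: MuA-style transposition with 5-bp target-site
    duplication and a 5'-depressed positional bias, FACS partition into
    surface-expressed and not-surface-expressed pools, junction read pairs,
    protein-property tables, and voltage-dye event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    bio3d,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    zoo,
    pROC,
    rpart,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
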
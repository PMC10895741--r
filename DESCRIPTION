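Package: beditr
Title: Base-Editor Guide Design and Editing-Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for plant base-editing experiments: design of base-editor
    guides with editing-window modeling and amino-acid-consequence (bystander)
    prediction, mismatch-tolerant PAM-aware off-target site enumeration,
    quantification of editing outcomes from amplicon deep-sequencing reads
    (per-position conversion rates, allele tables, chimera classification), and
    genome/transcriptome SNV off-target triage with background subtraction,
    editor-compatible filtering, predicted-site intersection and region
    annotation. Includes closed-loop synthetic-data generators (genomes with
    planted sites, gene models, programmed amplicon read pools, four-sample SNV
    designs) so every analysis can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
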
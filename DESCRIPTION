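Package: orfannot
Title: Prokaryotic ORF Prediction and Homology-Based Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts open reading frames (ORFs) in prokaryotic genomes with a
    single-pass six-frame finite state machine, transfers functional annotation
    from a local protein reference database by Smith-Waterman alignment, scores
    every hit with a composite accuracy metric combining identity with mutual
    query/subject coverage, refines start sites automatically against the best
    subject, resolves overlapping calls with a length-prioritized queue, applies
    three pre-curation filters (low accuracy, overlap, intergenic reduction),
    annotates tRNA and rRNA features from reference sequence sets, and exports
    curated EMBL feature tables.  Includes a deterministic synthetic-genome
    generator with planted, ground-truthed genes for validation, and supports
    re-annotation of existing EMBL or GenBank files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
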
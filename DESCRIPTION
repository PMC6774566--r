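Package: germfuse
Title: Identification, Filtering and Phenotype-Driven Prioritization of
    Germline Fusion Transcript Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A curation workflow for putative gene-fusion transcripts called
    from germline (non-tumor) RNA-seq. Raw fusion-caller output is retained
    under an inclusive read-support rule (one split plus one spanning read
    pair), screened against a normal-control fusion database and for
    cohort recurrence, reduced to one of eight alignment-pattern categories
    using tabular genome and transcriptome alignments of the full fusion
    contig and its decoupled segments, annotated for exon-boundary,
    reading-frame and read-through status against gene models, and ranked
    by phenotype relevance with a rank-score (rank divided by the number of
    scored disease genes). A deterministic synthetic-fixture generator
    builds a toy genome, annotation, planted candidates of every category
    and a control cohort so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
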
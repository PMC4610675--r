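Package: txcomplexity
Title: Transcript Complexity and Alternative-Splicing Analysis of Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Length-matched bootstrap enrichment of transcripts-per-locus for
    disease gene lists, GC-content window statistics at transcript boundaries,
    canonical splice-motif scanning, pairwise classification of alternative
    splicing events (skipped exon, alternative donor, alternative acceptor,
    other) with event-type proportion tests, and tissue-dominance enrichment of
    the highest-expressed isoform from transcript-by-tissue expression tables.
    Includes a synthetic annotation, genome, and expression generator with
    truth bookkeeping so every stage of the pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
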
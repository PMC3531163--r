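Package: gmrefine
Title: RNA-Seq-Guided Refinement of Gene Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Revises putative gene annotations against strand-specific RNA-Seq
    evidence: corrects exon-intron boundaries using junction-spanning reads and
    canonical splice dinucleotides (GT-AG, GC-AG, AT-AC), extends 5' and 3'
    untranslated regions from base-level read coverage, recovers exons missed by
    the annotation, and assembles novel intergenic transcripts from coverage
    islands linked by splice junctions. Audits the effect of boundary revisions
    on annotated open reading frames, including frame-restoring pairs of
    annotation errors, and evaluates revisions with splice-site motif matrices,
    poly(A)-signal positional profiles, coverage and conservation distributions,
    and summary accounting. Includes a deterministic synthetic-data generator
    that plants each error category with matching evidence for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
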
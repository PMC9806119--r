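Package: splicefid
Title: Splicing Fidelity Analysis from Splice-Junction Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fidelity of the splicing program from aligned
    RNA-seq splice-junction tables: discovery and classification of
    unannotated splice junctions relative to a reference annotation, per-exon
    inclusion levels (percent-spliced-in) and an exon commitment score,
    per-intron retention ratios and a gene-level retention burden,
    consequence classification of skipped exons (frame disruption, premature
    termination codons and the 50-nt nonsense-mediated decay rule, conserved
    protein-domain loss), hypergeometric overlap statistics between samples,
    and sequence-feature profiling (splice-site strength under a trainable
    position-weight-matrix scorer, lengths, GC content). Includes a seeded
    synthetic-data generator that emits a complete fixture bundle (genome,
    annotation, expression, junction tables, intron coverage, domain table)
    with known ground truth, so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
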
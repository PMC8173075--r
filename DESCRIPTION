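Package: gaedit
Title: Discovery and Differential Analysis of G-to-A RNA Editing from
    RNA-Seq Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies high-confidence G-to-A RNA editing events from
    per-sample samtools mpileup text: quality-aware variant calling with
    strand-bias and base-quality false-positive checks, a six-rule artifact
    and germline filter cascade (simple repeats and homopolymers,
    mitochondrial sites, splice-junction and INDEL proximity, known
    germline variants, allele-frequency genotype patterns) with rescue of
    catalogued editing sites, replication-based admission of events,
    codon-level consequence annotation, differential editing statistics
    between experimental groups, and enrichment of differential editing in
    multi-event genes. Includes a self-contained synthetic-study generator
    (reference genome, gene models, repeat mask, variant catalogues and
    pileups with planted editing, germline variation and alignment
    artifacts) so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
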
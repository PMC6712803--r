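Package: retroexome
Title: Detection of Somatic Retrotransposition of Endogenous Genes from
    Whole-Exome Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects somatic retrotransposition of intron-bearing endogenous
    genes (processed-pseudogene / retrocopy insertions) from paired-end
    whole-exome alignments, using intron-spanning read pairs whose ostensible
    template length is inflated by intron removal in the sample. Provides
    cohort-level comparison of events across parental-fibroblast/iPSC sample
    pairs (presence matrices, hierarchical clustering, per-chromosome and
    exclusive-event counts), 96-class trinucleotide mutational-signature
    construction from iPSC-versus-parent variant calls under depth and
    structural-region filters, read-backed cis/trans phasing of nearby variant
    pairs, and a deterministic synthetic-data generator (reference, gene
    models, SAM read pairs, VCF pairs) so every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
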
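Package: transcriptweld
Title: Full-Length Transcript Reconstruction for Metatranscriptomes Using
    Metagenome Annotations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs full-length, single-CDS transcript sequences from
    fragmented metatranscriptomic contigs by projecting their alignments onto
    coding regions annotated on metagenomic contigs from the same sample.
    Fragmented transcripts are merged, missing interior sequence is filled
    from the genome, intergenic overhangs are trimmed and operon-spanning
    contigs are split into per-gene transcripts. Transcripts that do not
    align to the metagenome are rescued by open-reading-frame screening and
    greedy identity clustering. Includes reference-based assembly evaluation
    (single-alignment capture fraction, inter-genome and same-genome-gap
    misassembly calls, completeness histograms), alignment-based abundance
    estimation in TPM, and a synthetic microbial community generator that
    emulates typical metatranscriptome assembly artifacts with full ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Metagenomics, Transcriptomics, Sequencing, Alignment, Software
RoxygenNote: 7.3.3
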
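Package: orseq
Title: Ectopic Olfactory Receptor Expression Profiling from RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies ectopic expression of olfactory receptor (OR) genes
    and pseudogenes across tissue panels from spliced RNA-seq alignments.
    Implements union-exon FPKM quantification over a pseudogene-aware gene
    model, an intergenic-background null for calibrating detection
    thresholds (FDR/FNR curves and their intersection), cross-tissue
    expression profiling (expressed, potentially expressed, exclusive and
    ranked targets), reproducibility statistics between data sets,
    neighbourhood dependence of OR expression, and splice-junction-based
    detection of chimeric read-through transcripts with reading-frame
    classification. Ships a synthetic-data generator producing toy genomes
    with known per-gene FPKM truth, uniform intergenic noise and planted
    chimeric junctions, so that every stage of the pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, Biostrings, knitr
Config/testthat/edition: 3
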
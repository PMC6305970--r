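Package: txharmonize
Title: Harmonizing Genome Annotations Against a Gold-Standard Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and improving genome annotations using a
    heavily curated reference species as the gold standard. Provides
    exon-level Jaccard similarity between annotations, multi-level
    sensitivity/precision comparison (base, exon, intron, intron chain,
    transcript, gene), RNA-seq coverage diagnostics of unannotated regions,
    an iterative grid-search harness for tuning a pluggable transcript
    assembler, SVM-based filtering of assembled gene models followed by
    merging with the reference annotation, two-stage SVM discovery of novel
    1:1 orthologs from synteny, tissue expression, intron structure and
    sequence similarity, and validation of annotations against full-length
    cDNA alignments. A seeded synthetic-data module generates genomes,
    annotations, reads, expression matrices and ortholog pairs with planted
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
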
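Package: editomeR
Title: Detection, Quantification and Differential Analysis of A-to-I RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies high-confidence adenosine-to-inosine (A-to-I) RNA
    editing sites from strand-specific RNA-seq read evidence combined with
    whole-genome-sequencing genotypes, applying a five-filter cascade
    (genomic SNP exclusion, splice-junction proximity, homopolymer runs,
    read-end position, and multi-mapping uniqueness). Quantifies per-site
    and overall editing, annotates sites with genomic features, recoding
    consequences, repeat families and neighbor-nucleotide context, calls
    differentially edited sites across developmental stages with Student's
    t-tests and Benjamini-Hochberg false discovery rate control, and
    assesses consequences of 3'-UTR editing for microRNA binding with a
    seed-weighted local-alignment target scanner and a nearest-neighbor
    duplex-energy model. A fully specified synthetic-data generator emulates
    a 3-stage by 3-replicate strand-specific study design with planted
    editing truth and planted artifact classes, making the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    ape,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
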
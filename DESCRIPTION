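Package: splicedelta
Title: Collapsed-Isoform Splice-Site Models and Variant Delta-Score Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for per-nucleotide splice-site modelling and splice-disrupting
    variant effect prediction. Builds collapsed per-gene splice-site annotations
    from GENCODE-dialect GTF (union of manually annotated isoforms), encodes
    one-hot training windows with flanking context, trains small residual
    dilated-convolution sequence models with an Adam schedule, annotates VCF
    variants with acceptor/donor gain/loss delta scores including principled
    alignment of indel prediction tracks back to reference coordinates, and
    evaluates variant predictions both as a binary classification task and at
    exact-effect resolution. Includes a deterministic synthetic genome/variant
    generator with motif-defined splice sites and a rule-based oracle predictor
    so the full pipeline is testable end to end, plus a generic sliding-window
    position-weight-matrix delta scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
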
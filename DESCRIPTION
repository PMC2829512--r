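Package: strainscan
Title: Ancestor-Versus-Evolved Genome Comparison from Short Single-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the genome of a laboratory-evolved microbial strain
    against its ancestor using single-end short-read resequencing data.
    Provides a synthetic-data generator that plants point mutations and a
    tandem-inverted segmental amplification with micro-homology junctions, an
    internal ungapped read mapper (with SAM ingestion for external data),
    depth-and-concordance heuristic SNP calling, copy-number detection by
    circular binary segmentation of binned, normalized read-depth ratios, and
    single-base breakpoint recovery by de Bruijn assembly of unmapped reads
    followed by split ungapped alignment, micro-homology classification and
    rearrangement-structure inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment
Config/testthat/edition: 3
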
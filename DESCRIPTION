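Package: medipdmr
Title: MeDIP-Seq Methylome Profiling and Seed-and-Extend DMR Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-group MeDIP-seq DNA methylation
    comparisons at small sample sizes: read-level quality filtering and
    multi-hit collapsing, CpG-site read-depth quantification with group-mean
    coverage filtering and library-size normalization, seed-and-extend
    detection of differentially methylated regions with a Bartlett-gated
    parametric/nonparametric site test and permutation-based
    Benjamini-Hochberg FDR control, annotation of regions to canonical gene
    features, chromosome- and gene-level methylome profiles with hierarchical
    sample clustering, and orthogonal-validation computations (bisulfite
    clone summaries, 2^-ddCt relative expression, fatty-acid composition,
    adipocyte volume). Includes a synthetic-data generator with planted
    regions and ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
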
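Package: chromprofiler
Title: Chromatin Time-Course Profiling: Coverage Normalization, Peak
    Algebra, Metagene Bootstrap Profiles and PolII Traveling Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of chromatin time-course
    sequencing experiments (ChIP-seq, MNase-seq, nascent RNA-seq).
    Converts aligned-fragment interval files into 1x-normalized (RPGC)
    coverage tracks with input subtraction and control-ratio
    normalization; performs peak-set algebra (co-bound unions, replicate
    consensus, all-dataset intersection, blacklist filtering) and
    enhancer/promoter classification from histone-mark peak sets; builds
    reference-point signal matrices and aggregate (metagene) profiles
    with per-location and flank-baseline normalization, bootstrap
    confidence intervals and empirical p-values; and computes per-gene
    RNA polymerase II traveling ratios with expression filtering and
    distribution comparison. A seeded synthetic-data generator emulates
    the statistical structure of ChIP, MNase, PolII and nascent-RNA
    libraries so the full pipeline runs and is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
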
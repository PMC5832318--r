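Package: lowpassCNA
Title: Single-Cell Copy-Number Profiling from Low-Pass Whole-Genome
    Sequencing of Restriction-Fragment Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide copy-number analysis of single cells
    sequenced at very low coverage after ligation-mediated PCR whole-genome
    amplification of restriction fragments. Implements an in-silico
    restriction-digestion genome representation model (MseI/TTAA), fixed-size
    binned read counting with longest-overlap assignment, LOWESS GC-bias and
    mappability normalization, panel-of-normals detection of problematic
    genome regions, piecewise-constant segmentation with rank- and
    distribution-based significance tests for copy-number alteration calling,
    and absolute main-ploidy estimation by kernel-density peak detection and
    linear regression of peak positions on integer copy numbers. A simulation
    module generates synthetic genomes and single-cell count data with the
    representation biases the workflow assumes, and an evaluation module
    computes windowed ROC/AUC, specificity and profile concordance.
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
    jsonlite
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
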
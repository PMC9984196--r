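Package: rnaloc
Title: Quantifying Subcellular RNA Localization from Fractionation,
    Sequence and Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of subcellular RNA localization.
    Computes log2 localization biases (cytoplasmic, apical/basal and
    neurite/soma) from fraction-level RNA-seq count matrices with
    median-of-ratios normalization and a negative-binomial Wald test with
    Benjamini-Hochberg false discovery control; scans 5' UTRs for
    pyrimidine-rich regulatory elements (5' TOP and PRTE motifs) and
    generates purine-swapped mutant sequences; builds dual
    spliced/unspliced transcriptome FASTA files from a genome and GFF3
    annotation; summarizes single-molecule FISH spot coordinates into
    per-cell apicobasal positions and neurite/soma puncta ratios;
    aggregates localization ratios across many fractionation datasets
    into a z-score meta-statistic (LRz) and correlates localization
    between cell types; and simulates all of these inputs with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
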
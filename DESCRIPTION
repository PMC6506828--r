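Package: chialink
Title: Pol II ChIA-PET Loop Calling and SOX2 Enhancer-Expression Co-Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline connecting RNA polymerase II mediated
    chromatin loops, SOX2 and enhancer-mark occupancy, and gene expression
    change in Sox2-deleted neural stem cells. Implements paired-end tag (PET)
    classification, deduplication and 1-kb interaction clustering with
    hypergeometric significance and Benjamini-Hochberg FDR; promoter, gene-body
    and intergenic anchor annotation with interaction typing; histone-mark
    region standardization, active/poised enhancer states, 200-bp Poisson bin
    binarization, chi-square differential bins, and random-sampling interval
    enrichment with mappability masking; expression fold ratios, differential
    grouping and Wilcoxon paired tests; and the signed Fisher co-association
    score linking downregulated genes to SOX2-bound promoter-enhancer loops.
    A synthetic-data generator with known ground truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
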
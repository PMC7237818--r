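Package: scregmap
Title: Virtual-Tissue Mapping of Single-Cell Omics and Enhancer-to-Gene Link Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps independently assayed single-cell transcriptomes and single-cell
    chromatin-accessibility profiles onto a shared virtual two-dimensional tissue
    template by pseudotime and landmark-distance binning. The co-located virtual
    cells are then used to infer signed enhancer-to-gene links (Pearson correlation
    with normal-fit percentile thresholds, combined with random-forest importances
    binarized by a step-function procedure), topic-model derived region-accessibility
    probabilities and gene-activity scores, enhancer specificity classes based on the
    gini index, and cell-type-resolved chromatin-accessibility QTL motif effects
    (allele-specific delta PWM scores with Fisher enrichment against control SNPs).
    Includes synthetic-data generators with planted ground truth for every pipeline
    stage.
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
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    ranger,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
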
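Package: ptcKit
Title: Enhancer-Interaction Models and Condensate Colocalization Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying putative transcriptional condensates (PTCs)
    and the enhancer pairs they contain. Fits three generative models of
    two-enhancer control of gene expression (additive, exponential and
    logistic) to replicate RT-qPCR-style measurements normalized to wild-type
    batch means, and compares them by the Bayesian Information Criterion.
    Quantifies colocalization of DNA-FISH spots with an immunofluorescence
    marker (such as BRD4) in confocal z-stacks via nucleus segmentation, spot
    detection, 3D stitching, a randomized-center null and 11x11 intensity
    window aggregation. Implements genome-category classification and
    enrichment statistics: TF-target enrichment scores, tissue-specificity
    rank scores, permutation SNP-overlap enrichment and hypergeometric module
    overlap, plus PTC gene filtering and timepoint-membership clustering.
    Includes seeded synthetic-data generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, GeneRegulation, CellBiology, Visualization
RoxygenNote: 7.3.3
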
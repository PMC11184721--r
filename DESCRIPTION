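Package: StromaQuant
Title: Quantitative Morphometry, Migration, Colony and Secretome Analysis
    for Stromal Cell Heterogeneity
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying heterogeneity in bone marrow stromal cell
    (BMSC) cultures. Implements label-free quantitative phase image processing
    (rolling-ball background removal, seed detection and consolidation, seeded
    segmentation, per-cell morphometry and dry-mass measurement), cell tracking
    with debris exclusion gates and migration metrics, automated detection and
    measurement of crystal-violet-stained CFU-F colonies in flatbed plate
    scans, reference-based morphometric subtype classification, and secretome
    statistics (total-intensity normalisation, differential abundance,
    matrisome annotation, chi-square enrichment, and gene-set
    over-representation). Seeded synthetic-data generators emulate phase
    time-lapses, plate scans and abundance tables with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    MASS,
    tiff,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Proteomics, Software
RoxygenNote: 7.3.3
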
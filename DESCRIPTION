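Package: retinaPheno
Title: Quantitative Phenotyping of Retinal Organoid Images and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and expression-comparison tools for phenotyping
    human retinal organoids: cell-composition counting on cross-section ROIs,
    photoreceptor mosaic geometry (Voronoi neighbours, spacing, density),
    radial lamination profiles, apical-boundary estimation with extruded-cell
    and inner-segment quantification, en-face marker area fractions, and
    fovea-versus-periphery assignment of single cells by correlation against
    reference mean expression vectors. Ships a synthetic-data generator that
    renders ground-truth images, cohorts, and expression matrices so every
    pipeline stage is verifiable by parameter recovery, plus cohort-level
    statistics (organoid-level means, inter/intra-organoid coefficients of
    variation, t-test and ANOVA with Tukey post hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deldir,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
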
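Package: gapstack
Title: Ensemble Species Distribution Models and Protected-Area Gap Analysis
    on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how well protection-area categories (full
    protection units, sustainable use units, indigenous lands) cover modeled
    species distributions. Provides a synthetic-landscape generator with known
    Gaussian niches, occurrence cleaning and Moran's-correlogram spatial
    thinning, PCA reduction of environmental predictor stacks, four suitability
    learners contrasted against envelope pseudo-absences or background points,
    Jaccard-gated ensemble averaging with basin-connectivity range constraints,
    a greedy core-area conservation prioritizer, grid-based protection
    classification by fractional coverage, per-species and cumulative
    protection percentages with one-way ANOVA, and a Monte Carlo randomization
    test of mean conservation importance inside protection classes. Rasters are
    read and written as plain-text ESRI ASCII grids; category maps export to
    GeoJSON.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    ape,
    pROC,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
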
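Package: uasPheno
Title: UAS Image Analysis for Field Pea Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for plot-level plant phenotyping from
    unmanned aerial system (UAS) imagery of pea breeding trials. Provides
    radiometric correction against a white reference panel, vegetation-index
    grids (GRVI, NDVI, NDRE, NIRv), crop-surface-model canopy metrics (canopy
    height, coverage and plot volume), zonal statistics over plot polygons,
    georeferencing quality metrics (horizontal and vertical position error),
    multi-temporal lodging scores, green-band leaf-type classification, and
    Lasso-based above-ground-biomass estimation. A synthetic-field module
    generates randomized-complete-block trials with known ground truth and
    renders multispectral band stacks and elevation surfaces, so every stage
    of the pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
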
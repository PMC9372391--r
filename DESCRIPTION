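Package: uavagb
Title: Multi-Dimensional Feature Extraction and Selection for UAV-Based
    Potato Biomass Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a UAV multispectral pipeline for
    estimating potato aboveground biomass (AGB, g/m2) at plot level. From
    six-band reflectance imagery (450-840 nm) it extracts spectral variables
    (six vegetation indices corrected for soil background by fully
    constrained linear spectral unmixing), texture variables (GLCM
    statistics screened over bands and ridge-relative directions),
    geometric variables (canopy height from DSM-DEM and fractional
    vegetation cover by the dimidiate pixel model or pixel classification),
    and frequency-domain variables (harmonic decomposition of the band
    spectrum). Candidate predictors are ranked by RReliefF, random-forest
    Gini importance, and out-of-bag permutation importance, and evaluated
    with partial least squares and random-forest regression over
    combinations of the four variable dimensions. A seeded synthetic-scene
    generator emulating a 48-plot factorial potato trial makes every stage
    verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    mixOmics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    quadprog,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
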
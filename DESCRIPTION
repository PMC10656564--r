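Package: canopymort
Title: Canopy Structure and Drought-Induced Tree Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline relating forest canopy structure to
    drought-induced tree mortality. Generates synthetic forest scenes (clustered
    stem maps with elevation-dependent genus niches, canopy height and terrain
    models, a known ground-truth mortality process), delineates individual tree
    crowns from the canopy height model by marker-controlled watershed
    segmentation, computes neighborhood competition indices (canopy cover taller
    than the central tree, cover taller than 66 percent of its height, and the
    coefficient of variation of neighbor heights), ray-traces crown shadow
    ratios under half-hourly solar geometry, derives terrain covariates (slope,
    aspect, D8 flow accumulation, topographic wetness index, clear-sky solar
    radiation), calls dead trees from crown dead-pixel fractions with threshold
    sweeps, and fits the statistical layer: weighted binning, weighted linear
    and piecewise (segmented) regression with breakpoint search, beta
    regression, random-intercept mixed models, bootstrap mediation analysis,
    and random-forest importance with partial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    lme4,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
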
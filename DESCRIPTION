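Package: benthoscape
Title: Deep-Water Benthic Habitat and Lobster Species-Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Terrain analysis and hierarchical species-distribution modelling for
    deep-water benthic habitats. Derives a twenty-layer predictor stack (detrended
    bathymetry, slope, aspect, curvatures, Jenness surface area, focal, hypsometric,
    range and standard-deviation statistics) from a bathymetry raster; fits
    deviance-based binary classification trees with ten-fold cross-validation
    cost-complexity pruning; evaluates models with ROC analysis, bootstrap AUC
    confidence intervals and the sensitivity/specificity-balancing P-fair threshold;
    assesses spatial dependence with indicator semivariograms and block-based
    spatially independent validation splits; and chains substrate, benthic biota and
    lobster presence/absence models into full-coverage habitat maps. Ships a seeded
    synthetic seascape generator (depth gradient, reef ridge, rugose patches, towed
    video transects, pot-line surveys, Poisson pot catches) so the whole pipeline is
    reproducible without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tree,
    pROC
Config/testthat/edition: 3
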
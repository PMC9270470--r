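Package: cavorient
Title: Directional Ecology of Woodpecker Cavity Orientation
Version: 0.1.0
Authors@R: person("Cavorient", "Maintainers", email = "maintainers@cavorient.org",
    role = c("aut", "cre"))
Description: Circular-statistics pipeline for analysing entrance orientations of
    woodpecker excavations: vector-addition circular summaries and Rayleigh
    tests, resampling null models for stage-wise directional clustering,
    latitudinal and climatic gradient analyses of population mean direction
    (OLS, climate PCA, permutation partial Mantel test, sunset-azimuth
    contrast), and harmonic sine/cosine Poisson and binomial mixed models
    linking nest-cavity direction and breeding-group size to reproductive
    success, with top-down likelihood-ratio model selection. Includes a von
    Mises synthetic-data generator emulating the statistical structure of
    red-cockaded woodpecker monitoring data and a command-line interface
    chaining the analysis stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
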
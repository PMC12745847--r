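Package: woodgen
Title: Spatial Population Genetics of a Nestbox Songbird Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time, spatially explicit simulation of a continuously
    monitored nestbox bird population (annual turnover, sex-biased natal
    dispersal, external immigration, ZW sex chromosomes with recombination),
    together with the population-genetic analyses such monitoring data
    support: genotype quality control and LD pruning, method-of-moments
    identity-by-descent and KING-robust kinship, runs of homozygosity,
    isolation-by-distance decay curves with kin stripping and penalized-spline
    fits, temporal renewal of spatial genetic structure, random-forest
    classification of immigrants versus locally born birds, and windowed
    Weir-Cockerham F_ST scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    randomForest,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
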
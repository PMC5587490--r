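Package: atlaseffort
Title: Sampling-Effort Bias and Inventory Completeness for Gridded
    Biodiversity Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify spatial and environmental bias in
    volunteer sampling effort for checklist-based biodiversity atlases
    on 5-arc-minute ("pentad") grids. Stratifies an atlas region into
    environmental zones by climate principal components and dominant
    biome, tests the evenness of sampling across zones with G-tests,
    models visit counts as a quasi-Poisson function of accessibility
    and land-cover covariates, and estimates per-zone inventory
    completeness from exact (Mao Tau) species-accumulation curves
    fitted to asymptotic Lomolino, Clench and Weibull models. Includes
    a fully seeded synthetic-atlas generator with recorded ground
    truth for validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
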
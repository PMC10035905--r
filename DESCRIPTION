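Package: prosoclim
Title: Agro-Climatic Sensitivity Analysis for Proso Millet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A process-based pipeline for assessing the climate sensitivity
    of Proso millet (Panicum miliaceum) in tropical monsoon environments.
    Provides daily weather series input/output and gap filling, a stochastic
    weather generator calibrated to bimodal-monsoon climate normals, a
    simplified thermal-time and water-limited crop simulator parameterised
    by accession-specific genotype coefficients, a 99-member Latin-hypercube
    temperature-by-rainfall sensitivity design with quadratic impact
    response surfaces, delta-method application of general circulation
    model change signals with ensemble statistics, and gridded yield
    mapping with inverse-distance-weighted interpolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lhs,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
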
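Package: paddletox
Title: Voltage-Sensor Paddle Gating, Toxin Occupancy and Lipid Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of gating-modifier toxin pharmacology on
    voltage-gated channels studied by two-electrode voltage clamp and
    tryptophan fluorescence. Fits Boltzmann voltage-activation curves from
    tail or peak currents, estimates resting-state toxin occupancy (fraction
    unbound, apparent Kd, binding-site stoichiometry) under an
    equal-and-independent-sites model, and quantifies toxin-membrane
    interaction as a mole-fraction partition coefficient from fluorescence
    titrations. Includes a synthetic-data generator that emulates
    voltage-clamp current families, dose-response tables and emission
    spectra, so every analysis stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
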
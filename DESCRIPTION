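Package: mmcontrol
Title: Metabolic Model Control for Fed-Batch Algal Nutrient Feeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-driven nutrient feeding for microalgal cultures. Estimates
    growth rates from optical density time series, constrains a constraint-based
    metabolic model to the observed growth rate, inverts the flux balance
    analysis objective to minimize nitrate uptake (or lexicographically glucose
    then nitrate under heterotrophy), and converts the minimized uptake fluxes
    into per-interval feed masses. Includes a parameterized toy metabolic
    network with composition-derived biomass stoichiometry, biomass-composition
    editing for nitrogen-limited operation, an empirical polynomial cap on
    glucose uptake versus accumulated biomass, a quota-model virtual culture
    for closed-loop testing, feed accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
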
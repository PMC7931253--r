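Package: foodexch
Title: Food Composition Auditing and Dietary Exchange List Derivation
Version: 0.1.0
Authors@R:
    person("foodexch", "maintainers", email = "maintainers@foodexch.invalid",
           role = c("aut", "cre"))
Description: Tools for working with proximate food-composition tables and
    deriving meal-planning exchange lists from them. Completes proximate
    rows by carbohydrate-by-difference, computes Atwater energy and
    Kjeldahl protein, audits tables for mass-closure and energy
    inconsistencies, profiles foods as percent daily value with FDA-style
    nutrient-content claims, and derives exchange-list entries (Wheeler
    round-off serving bands, grams-per-exchange serving sizes,
    quarter-exchange quantization, per-serving scaling). Ships a
    65-food Eastern Mediterranean reference fixture, a seeded synthetic
    composition generator with controlled closure corruption, and a
    command-line pipeline (validate, analyze, exchanges, simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
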
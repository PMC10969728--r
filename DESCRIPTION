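Package: relkin
Title: Emulsion Stability and Encapsulated-Oil Release Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Modeling chain for hydrocolloid-stabilized essential-oil
    emulsions and their spray-dried, monolith-embedded powders: emulsion
    stability indices from turbidimetric absorbance, zero- and first-order
    kinetic fits of stability decay across storage temperatures, two
    independent routes to effective diffusivity for a plane-slab monolith
    (first-order rate-constant conversion and truncated Fickian
    eigenfunction-series fitting), spray-drying process yield and
    encapsulation-efficiency arithmetic, and Pearson correlation analysis
    of sample-level formulation parameters. Includes a seeded synthetic-data
    generator for stability trajectories and slab-release curves so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
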
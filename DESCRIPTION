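Package: terpsle
Title: Solid-Liquid Equilibrium Modelling of Dehydroabietic Acid in
    Terpene Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Correlates and analyses the mole-fraction solubility of
    dehydroabietic acid in terpene solvents. Implements the modified
    Apelblat, Buchowski lambda-h, van't Hoff, NRTL, UNIQUAC, modified
    Wilson and Wilson-van't Hoff solubility models with deterministic
    multistart least-squares fitting, deviation metrics (RD, ARD, RMSD),
    AIC-based model selection with Akaike weights, van't Hoff dissolution
    thermodynamics (enthalpy, entropy and Gibbs energy of solution and
    their weights), and Fedors group-contribution Hansen solubility
    parameter screening. Ships the measured datasets for
    (-)-alpha-pinene, p-cymene and (-)-beta-caryophyllene systems and a
    synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
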
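Package: cosmopharm
Title: COSMO-SAC and Hansen/Flory-Huggins Solid-Liquid Equilibria for
    Pharmaceutical Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Activity-coefficient driven solid-liquid equilibrium workflow for
    drug-like molecules: parsing and writing COSMO cavity-surface files,
    sigma-profile generation (charge averaging, 51-bin histogramming and the
    NHB/OH/OT hydrogen-bonding split), activity coefficients from the original
    and the temperature-dependent revised COSMO-SAC models and from a
    Hansen-parameter Flory-Huggins model, and downstream solubility,
    octanol/water partition-coefficient and cocrystal ternary phase-diagram
    calculations, together with model-vs-experiment error statistics and a
    synthetic-data generator for toy cavity surfaces and noisy solubility
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
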
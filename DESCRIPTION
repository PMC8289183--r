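Package: tacit
Title: Kinetics and Process Design for Tannic Acid-Citrate Gold Nanoparticle Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Process-engineered modelling of ultrasmall gold nanoparticle (uGNP)
    synthesis by the combined tannic acid (TA) and sodium citrate reduction
    method. Implements triprotic citrate speciation, a mass-action kinetic
    mechanism for competing reduction (TA and citrate routes) and hydroxide
    passivation of the tetrachloroaurate precursor, selectivity-based
    final-diameter prediction, seeded-growth process bookkeeping (particle
    number concentrations, surface areas, theoretical diameters, dosing
    schedules, equal-surface-area dilution factors), RGB-colorimetry reaction
    progress analysis with initial-rate and reaction-order estimation, and
    synthetic-data generators (kinetic traces, reaction frame series,
    TEM-like size samples) for end-to-end testing without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
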
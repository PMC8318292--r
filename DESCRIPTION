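Package: colonergy
Title: Two-Compartment Gastrointestinal Energy-Flux Model of Colonic
    Microbial Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stoichiometry-based model of host-microbiome energy balance
    across the upper and lower gastrointestinal tract. Tracks dietary
    macronutrients as chemical oxygen demand (COD) electron equivalents,
    applies a piecewise small-intestine absorption model parameterized by
    the fraction of intestine surgically removed, ferments the ileocecal
    output in a single-chemostat colon with first-order hydrolysis
    kinetics and fixed short-chain fatty acid (SCFA) stoichiometry, and
    reports metabolizable energy recovery. Includes least-squares
    parameter estimation from clinical-style observation tables and a
    synthetic-cohort generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
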
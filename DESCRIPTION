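Package: electrofba
Title: Constraint-Based Simulation of Microbial Electrosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study electrically enhanced fermentation
    (microbial electrosynthesis) with genome-scale metabolic models.
    Augments a stoichiometric model with an electrode electron-uptake
    exchange and a cytoplasmic NADH-regeneration reaction, solves flux
    balance analysis problems with a built-in bounded-variable simplex,
    and quantifies the effect of cathodic electron supply on ATP yield,
    growth rate, theoretical product yields, production envelopes and
    growth-coupled strain designs. Includes the substrate-product
    electron equivalence quotient (SPEEQ) redox metric, a library of
    heterologous production pathways (1,3-propanediol, 1,4-butanediol,
    n-butanol, Wood-Ljungdahl CO2 fixation), SBML Level 3 (FBC) and
    BiGG-style JSON model input/output, and an analytically solvable
    synthetic fermentation network used as a test oracle.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
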
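Package: cardiox
Title: Electro-Mechano-Energetic Simulation of hiPSC-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-cell simulator of human induced pluripotent stem cell derived
    cardiomyocytes (hiPSC-CMs) coupling Paci-family action-potential
    electrophysiology to a metabolite- and pH-sensitive two-state thermodynamic
    SERCA pump, a mean-field metabolite-sensitive crossbridge contractile
    element, an ATP-sensitive potassium current and an extracellular oxygen
    balance. Ships ischemia (two severities), ischemia-reperfusion and
    levosimendan protocols, beat-resolved biomarker extraction (action
    potential, calcium transient, tension and energetic metrics, early
    afterdepolarization and aftercontraction detectors), tidy trace output and
    a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
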
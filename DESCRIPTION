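Package: ikursim
Title: Atrial I_Kur Channel Variants, Voltage-Clamp Fitting, and
    Multi-Scale Arrhythmia Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the atrial-specific ultra-rapid delayed rectifier
    potassium current (I_Kur, Kv1.5, gene KCNA5) and six naturally
    occurring gain- and loss-of-function variants.  Provides a
    voltage-dependent Hodgkin-Huxley formulation of I_Kur with Q10
    temperature correction, simulated whole-cell voltage-clamp
    protocols, synthetic clamp-trace generation with known ground
    truth, Boltzmann and mono-exponential curve fitting, two human
    atrial action-potential models (Courtemanche-lineage and
    Grandi-lineage) with regional, chronic-AF and beta-adrenergic
    variants, and 1D/2D monodomain tissue simulation for conduction
    velocity, S1S2 vulnerability windows, sinus-driven conduction
    patterns, and re-entry dynamics with dominant-frequency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    minpack.lm,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
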
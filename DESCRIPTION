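Package: tmsd
Title: Kinetics and Thermodynamics of Mismatch-Elimination DNA Strand Displacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models toehold-mediated strand displacement (TMSD) reactions in
    which an internal base-pair mismatch in the substrate duplex is eliminated
    by the invading strand. Provides nearest-neighbour duplex thermodynamics
    with internal-mismatch parameters and duplex-end fraying, free-energy
    profiles of displacement intermediates, a discrete-state Markov-chain
    landscape model with exact splitting probabilities and mean first-passage
    times, kinetic Monte Carlo and forward flux sampling estimators,
    mass-action ODE models of the rate-assay, catalytic toehold-exchange and
    pulse-generator circuits with nonlinear least-squares fitting of
    fluorescence traces, and a synthetic spectrofluorimeter-trace generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    withr,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
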
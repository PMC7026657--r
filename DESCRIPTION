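Package: quadkin
Title: Four-State Kinetics of Hairpin to G-Quadruplex Conformational Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the K+-induced conformational transition of a WNT1-promoter
    G-rich sequence from a hairpin through an intermediate G-quadruplex G4(I)
    to a final G4(II) via an unfolded ensemble, as a linear four-state
    first-order kinetic network. Provides the exact eigendecomposition solution
    of the rate equations, detailed-balance equilibrium populations and slow
    relaxation times, a constrained dual-wavelength global fit of circular
    dichroism (CD) kinetic traces recovering the folding rates k2 and k3 with
    k1, k4, k5 fixed from arising-time and hydrogen-deuterium exchange (HDX)
    measurements, single-exponential arising/HDX fitting, first-derivative
    melting-temperature extraction from CD melting curves, conformer population
    estimation from imino-proton peak volumes, and seeded synthetic-data
    generators for every input so the whole pipeline is testable end to end.
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
    Matrix,
    minpack.lm,
    pracma,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
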
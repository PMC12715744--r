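Package: phiptools
Title: Simulation and Analysis Toolkit for Parahydrogen-Based Hyperpolarizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization workbench for parahydrogen-induced polarization
    (PHIP) instruments operating at low magnetic field. Provides a small
    density-matrix simulator for spin-1/2 systems with ideal pulses and free
    evolution, the out-of-phase echo (OPE) spin-order conversion sequence and
    its inter-pulse delay optimization, Gaussian-ensemble modelling of B1
    inhomogeneity from nutation curves, CPMG relaxometry with an effective
    diffusion-homogeneity term, a hydrogenation-kinetics model, polarization
    accounting against a thermal reference, reactor fill-volume geometry, and
    seeded synthetic-data generators so every fitting stage can be validated
    by parameter-recovery round trips.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
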
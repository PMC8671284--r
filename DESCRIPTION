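Package: rcrtune
Title: Three-Element Windkessel Outlet Boundary Condition Tuning and
    Uncertainty Propagation for Aortic Coarctation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrates total three-element Windkessel (RCR) lumped
    parameters from catheter pressure statistics and an inlet flow waveform
    with a constrained genetic algorithm, distributes them to the outlets of
    an aortic-coarctation model by cross-sectional area with a
    coarctation-area substitution, redistributes flow with a dimensionless
    split value, runs a 0D single-junction forward model, and propagates the
    split-value uncertainty with generalized polynomial chaos
    (Gauss-Legendre collocation, Legendre basis), yielding stochastic means,
    standard deviations and probability density maps of outlet flows,
    pressure drop and time-averaged wall shear stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
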
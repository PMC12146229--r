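Package: cyclematch
Title: Matching a Maturity-Structured PDE Model of the Cell Cycle to a
    Two-Compartment ODE Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical tools for a maturity-structured transport PDE model of
    cell-cycle progression with piecewise-constant phase velocities, and for
    its reduction to a linear two-compartment (G1/G2) ODE model. Provides the
    exact piecewise solution of the PDE by the method of characteristics,
    phase counts and proportions, population growth rates, cycle-averaged
    observables and oscillation extrema; the ODE model's closed-form solution,
    steady-state phase proportion and long-term growth rate; the forward and
    (multi-valued) inverse parameter-matching map between the two models;
    variance-based global sensitivity analysis of the matched rates (Sobol'
    indices via Saltelli sampling with a dummy-input control); generation of
    synthetic discretely-sampled PDE trajectories; and multistart nonlinear
    least-squares calibration of the ODE model to such data on a log scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    lhs,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
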
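Package: nosc
Title: Stability, Bifurcation and Frequency Analysis of Two-Variable
    Neuronal Oscillator Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for planar (two-variable) neuronal oscillator circuits:
    the FitzHugh-Nagumo neuron model and S-type negative-differential-
    resistance (NDR) memristive oscillators under constant-current or
    constant-voltage drive. Provides stationary curves, nullclines and fold
    points; linearization with trace-determinant classification and
    closed-form Hopf-bifurcation boundaries (critical capacitance,
    time-constant ratio, load resistances); analytic oscillation
    frequencies near the Hopf point and relaxation-oscillation periods by
    slow-branch loop integrals; stiff-capable direct simulation with
    limit-cycle period and amplitude extraction; and one-parameter sweeps
    producing bifurcation boundaries, amplitude envelopes and
    frequency-versus-capacitance curves. A small command-line driver with
    named parameter presets, JSON configuration and CSV/JSON output is
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
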
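Package: nfosc
Title: Exact and Analytical Solutions for Negative-Feedback Ring Oscillators
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying a general n-species negative-feedback
    oscillator with unit-step (on/off) regulation. Provides an exact
    event-driven simulator of the piecewise-linear dynamics, a
    semi-analytical solver for the limit-cycle period and amplitudes via
    the cycle-closure integral constants, closed-form period, amplitude
    and multiparameter-sensitivity (MPS) expressions under the saturating
    peak/trough approximation, generic finite-difference sensitivity and
    Monte-Carlo variance machinery, and scripted validation sweeps across
    random parameter sets and loop lengths.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
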
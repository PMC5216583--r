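Package: epgopt
Title: Optimal-Control Design of Turbo Spin-Echo Flip-Angle Trains via
    Extended Phase Graphs and Adjoint-State Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the extended phase graph (EPG) of a multi spin-echo
    sequence as a discrete-time dynamical system and designs flip-angle and
    phase trains (including multi-channel parallel-transmit drives) by
    constrained nonlinear minimization. Exact derivatives of all objective
    and constraint functions with respect to pulse amplitudes, phases and
    per-channel complex weights are computed with the adjoint-state method
    at a cost of about four EPG simulations per gradient, independent of the
    number of design parameters. Ships building-block objectives and
    constraints (target-error, signal maximization, total and peak RF
    power), piecewise-constant parameter grouping, a spatially resolved EPG
    for parallel transmit with a synthetic multi-channel transmit-field
    generator, an augmented-Lagrangian solver with exact gradients, and
    preset design experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
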
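Package: capres
Title: Analytical Residue Functions for Cerebral Capillary Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tracer kinetics in synthetic cerebral capillary
    networks. Generates random capillary beds inside a tissue cube that
    match published human cortical morphometry, solves steady Poiseuille
    flow with a diameter-dependent apparent blood viscosity at fixed
    haematocrit, and computes the exact piecewise-constant residue
    function R(t) of the perfused network by dynamic programming over the
    flow-directed acyclic graph (a sum of rectangular contributions, one
    per vessel per upstream pathway). Derives the transit-time
    distribution h(t), mean transit time, capillary transit-time
    heterogeneity (CTTH), and perfusion metrics (CBF, CBV, MTT), fits
    gamma-mixture characterizations of R(t) by constrained nonlinear
    least squares, and orchestrates paired healthy-versus-occluded
    ensemble experiments with summary statistics and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
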
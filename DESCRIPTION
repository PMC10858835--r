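Package: aggmeta
Title: Long Transients and Asymptotic States in Aggregation-Diffusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical and analytic tools for one-dimensional
    aggregation-diffusion equations with nonlocal advection on a periodic
    domain. Provides conservative finite-volume right-hand sides for the
    nonlocal model, its fourth-order moment-closure (Cahn-Hilliard type)
    approximation and a logistic-growth variant; a forward-Euler integrator
    with mass tracking and steady-state detection; the associated energy
    functional and dissipation rate; closed-form piecewise-cosine critical
    points of the energy (single and twin aggregation peaks) with their
    closed-form energies; and diagnostics that distinguish long-transient
    from candidate-asymptotic states, including peak detection, merge and
    decay times, and a bisection finder for the critical logistic growth
    rate at which a smaller peak switches from decaying to persisting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
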
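Package: softmodes
Title: Simple Integral-Feedback Controllers and the Evolution of Soft Modes in Gene Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Anonymous", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how low-dimensional (simple) proportional-integral
    feedback controllers regulate high-dimensional gene regulatory networks.
    Provides a nonlinear Michaelis-Menten network simulator with environmental
    forcing and k-channel integral feedback, fixed-point and Jacobian eigenmode
    analysis (mode gap, soft modes), an analytic linear theory of controlled
    perturbation responses with closed-form expected deviations and optimal
    sensing/action geometry, in-silico evolution of network parameters by
    simulated-annealing MCMC under selection for homeostasis, and two
    prediction experiments: dual buffering of environmental and mutational
    perturbations, and the reduction of response dimensionality following
    controller knockout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
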
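Package: translokit
Title: Polymer Translocation Through Nanopores: Barrier, Flux and Langevin Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the passage of a linear polymer through a nanometre-scale
    membrane pore. Provides the entropic/chemical-potential free-energy barrier
    over the threading coordinate, a closed-form steady-state flux through a
    parabolic barrier with linear friction (validated against adaptive
    quadrature), an exponentially fitted finite-volume solver for the
    drift-diffusion (Smoluchowski) equation with first-passage-time
    observables, a driven bead-spring Langevin simulator built on the exact
    Ornstein-Uhlenbeck propagator, and estimators for the chain-statistics
    exponents (partition exponent gamma, Flory exponent nu, translocation-time
    scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
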
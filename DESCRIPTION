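Package: teaps
Title: Thorough Exploration of Allowable Parameter Space for Stable
    Biological ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds the set of kinetic-parameter combinations under which an
    ordinary-differential-equation model of a biological system is biologically
    stable and resilient: the system has a prescribed fixed point, a locally
    contracting neighbourhood around it, and a bounded relaxation timescale.
    Implements the TEAPS search scheme (cluster-Newton candidate collection
    followed by globalized limited-memory BFGS with noise-add/re-optimize
    loops over a growing observation region), Monte-Carlo basin-stability
    estimation, brute-force and random-vector reference searches with analytic
    fixed-point reduction, and kernel-density/PCA comparison of the resulting
    parameter-set distributions. Eight self-contained benchmark models are
    built in, and SBML models can be imported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
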
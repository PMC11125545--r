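Package: twitchsim
Title: Kinetic Monte Carlo Simulation and Likelihood-Free Inference for
    Type IV Pili Driven Bacterial Twitching Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A three-dimensional kinetic Monte Carlo model of twitching
    motility in rod-shaped bacteria such as Pseudomonas aeruginosa, in
    which type IV pili (TFP) anchored around the leading pole extend as
    worm-like chains, bind the surface at their tips and retract under a
    molecular-motor state machine, dragging a rigid spherocylindrical
    cell body whose pose is relaxed to mechanical equilibrium after every
    event.  The package also provides the trajectory toolchain built on
    top of the simulator: fixed-length linearisation of pole tracks,
    persistent-random-walk summary statistics, mean-squared-displacement
    exponents, walking/crawling classification, Sobol total-effect
    sensitivity analysis over the model parameters, and rejection
    approximate Bayesian computation with Epanechnikov-weighted kernel
    density posteriors for parameter inference from tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
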
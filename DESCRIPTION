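Package: netphase
Title: Phase Transitions in Particle Systems Coupled by Dynamical Spring Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying aggregation in systems of overdamped Brownian
    particles that interact through a dynamical network of elastic links.
    Implements the stochastic agent-based simulator (particles on a periodic
    domain with randomly created and destroyed spring links and its
    instantaneous-relinking limit), the macroscopic aggregation-diffusion
    equation obtained in the fast linking/unlinking regime with its compactly
    supported spring potential, positivity-preserving well-balanced
    finite-volume solvers in one and two dimensions, and the linear and weakly
    nonlinear stability analysis of the uniform state: Fourier modes of the
    potential (closed form in 1D, Bessel-Struve form in 2D), critical noise
    and spring-length thresholds, supercritical/subcritical bifurcation
    classification, and saturated amplitude predictions.  Experiment drivers
    regenerate threshold tables, bifurcation diagrams Q(D), steady-state
    residual traces and micro-macro density overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
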
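Package: isnet
Title: Inhibition-Stabilized Attractor Networks as Finite-State Machines
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing networks of bistable
    inhibition-stabilized excitatory-inhibitory rate-unit pairs.  Provides
    closed-form fixed-point and stability analysis of a single pair,
    constrained random weight-matrix generation under Dale's law, rectified
    fourth-order Runge-Kutta integration of the network rate equations,
    enumeration of point attractors and exponential fits of state-count
    growth, stimulus-evoked transition graphs with itinerancy measures and
    a stimulus-tolerance statistic, and extraction and scoring of the
    finite-state machine that a network implements on a two-alternative
    evidence-accumulation task (reliability, psychometric curves,
    primacy and recency).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
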
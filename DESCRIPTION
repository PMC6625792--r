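Package: tastedyn
Title: Ensemble State Dynamics and Orofacial Behavior in Cortical Taste Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured gustatory-cortex
    electrophysiology and jaw electromyography. Detects single-trial
    ensemble state transitions (detection, identity, palatability) in
    spike trains with a constrained two-change-point model fit by
    multi-restart hard Expectation-Maximization over categorical
    emissions; quantifies optogenetic perturbation effects on single-neuron
    firing with a hierarchical Bayesian Poisson GLM; tracks palatability
    coding over time with per-bin Bayesian regression and a logistic
    sigmoid time-course model; and estimates the onset of aversive
    orofacial behavior (gaping) from EMG envelopes via Bayesian spectrum
    analysis, Beta-distribution Kullback-Leibler divergence, and a
    Bayesian piecewise-linear change-point. Includes a synthetic-data
    generator emulating the latent structure every stage assumes, so the
    full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    rjags,
    coda,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
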
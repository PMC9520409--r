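Package: avnodenet
Title: Dual-Pathway Atrioventricular Node Network Simulation with Autonomic Tone
Version: 0.1.0
Authors@R: person("avnodenet", "developers", email = "avnodenet@example.org",
    role = c("aut", "cre"))
Description: Discrete-event simulation of impulse propagation through a
    21-node network model of the human atrioventricular node during atrial
    fibrillation, with recovery-dependent refractory periods and conduction
    delays and multiplicative autonomic-tone scaling of both.  Includes a
    Pearson Type IV atrial-impulse generator with time-varying moments,
    RR-series characteristics (mean, RMSSD, sample entropy) with
    ectopic-interval exclusion, a distribution-based (Kolmogorov-Smirnov)
    global sensitivity analysis with a dummy-parameter significance
    threshold, and a head-up/head-down tilt-test simulation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
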
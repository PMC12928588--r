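Package: fleetkit
Title: Fault-Tolerant Orchestration of Data-Acquisition Fleets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale orchestration of experiment-control and online analysis
    pipelines. Hardware and data components are wrapped in fault-tolerant
    "vessels" connected by two graphs: a dependency (link) graph that governs
    startup order and contains failures by cascading invalidation, and a data
    graph that multicasts typed, metadata-stamped messages through bounded
    FIFO inbox queues. Includes a fleet-scoped services pool with settings,
    logging and metadata collection; a waveform-sequencing model for
    hardware-control patterns with virtual instruction channels; a synthetic
    online fish-tracking demonstration fleet with ground truth; and a
    framework-overhead benchmark with a no-intercept regression estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    R6,
    Rcpp,
    igraph,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
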
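Package: fgstdp
Title: Behavioral Simulation of Floating-Gate STDP Synaptic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven behavioral simulator of a floating-gate (FG)
    synaptic circuit that implements weight-dependent, pair-based
    spike-timing-dependent plasticity (STDP). Provides charge-relaxation
    models of tunnel-junction FG nodes (relaxation and retention times,
    single-anchor calibration), a behavioral synapse with spike-triggered
    sampling, injection thresholds, detailed-balance storage dynamics and a
    saturating voltage-transfer characteristic, Stein point neurons with
    exact event-driven integration, Poisson and binned alternating spike
    sources, competition and supervised-learning network protocols,
    statistical phase-plane (weight-plane) vector-field estimation, and
    Pelgrom/line-edge-roughness device-mismatch Monte Carlo propagated to
    behavioral synapse parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
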
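# fgstdp

Event-driven behavioral simulation of a floating-gate (FG) CMOS synaptic
circuit that implements pair-based, weight-dependent spike-timing-dependent
plasticity (STDP).

The circuit this package models stores its synaptic state on three
floating gates: two fast FG leaky integrators hold the pre- and
postsynaptic spike traces (the state variables of the pair rule), and a
slow FG node stores the analog weight. Charge tunnels off each FG through
a thin oxide barrier, which sets the biologically plausible relaxation
times of the traces and the tens-of-seconds retention of the weight.
`fgstdp` reproduces the circuit's behavioral repertoire — plasticity
induction, the timing-window curve, weight-dependent saturation, synaptic
competition, supervised steering by a bias neuron, and device-mismatch
ensembles — without transistor-level simulation, for computational
neuroscientists and neuromorphic designers who want to study the
plasticity rule rather than the silicon.

## The model in brief

* **Pair rule.** A weight change per pre/post spike pair follows
  `Δw(Δt) = A₊ s_pre(Δt)` for `Δt > 0`, `−A₋ s_post(−Δt)` for `Δt < 0`,
  and 0 at `Δt = 0`, with exponentially decaying state variables.
  Fitting the simulated single-pair curve returns LTP/LTD time constants
  of 16.8 and 76.5 ms.
* **Weight dependence.** Storage injection is self-limiting (detailed
  balance) and the stored level maps to the weight through a saturating
  transfer characteristic bounded in 0–0.5 V, so the pair rule weakens as
  the weight approaches either pole; under bidirectional 20 Hz pairing
  (1 ms offset) the causal synapse plateaus near 0.27 V while the reverse
  one decays to zero.
* **Networks.** A Stein point neuron (τ_m = 10 ms, threshold 90 mV,
  jump α·w with α = 0.3) is integrated exactly event-to-event; Poisson,
  binned-alternating and bias sources drive two-afferent competition
  experiments, with phase-plane (weight-plane) vector fields estimated
  statistically.
* **Mismatch.** Pelgrom threshold-voltage mismatch
  (σ = A_RDF/√(LW), 15 mV at 60 × 120 nm) and line-edge-roughness length
  variation (σ = A_LER/√W, ≈3 nm at W = 120 nm) propagate to the
  behavioral parameters in configurable first-order fashion for
  Monte-Carlo ensembles.

## Worked example

```r
library(fgstdp)

# single-pair STDP curve of the default-calibrated synapse
fit_stdp(stdp_curve(synapse_params()))
#> <stdp_fit> A+ = 0.0186 V, tau+ = 16.8 ms | A- = 0.00896 V,
#>            tau- = 76.5 ms | rms 0.00045 V

# bidirectional 20 Hz pairing, 1 ms offset, 100 s
tr <- protocol_bidirectional_pairing(duration_s = 100)
mean(tr$weights[tr$times >= 90, "N1->N2"])  #> 0.2681  (plateau, V)
tr$terminal[["N2->N1"]]                     #> 0       (reverse synapse)

# unsupervised two-afferent competition at 5 Hz for 150 s
protocol_unsupervised(duration_s = 150, seed = 1)
#> <fg_trace> 2 synapses over 150 s; terminal: w1 = 0.325 V, w2 = 0.107 V
```

The fitted windows say depression integrates spike timings over a
four-times-wider window than potentiation; the pairing run shows the
weight-dependent rule self-limiting at 0.27 V instead of the 0.5 V rail;
and the competition run shows one afferent capturing the postsynaptic
neuron while the other disconnects, with the winner chosen at random
across seeds.

A command-line front end with the same functionality lives at
`inst/cli/fgstdp.R` (subcommands `device`, `stdp-curve`, `fit`, `pair`,
`compete`, `alternate`, `supervise`, `phase-plane`, `mc`, `fixtures`),
configured through YAML files such as
`inst/extdata/default-config.yaml`. The methods vignette
(`vignettes/fgstdp-methods.Rmd`) documents the model, its calibration and
its limitations.

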
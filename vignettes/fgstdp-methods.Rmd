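---
title: "Behavioral modeling of a floating-gate STDP synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral modeling of a floating-gate STDP synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgstdp)
```

# The system being modeled

`fgstdp` is a behavioral (circuit-free) simulator of a CMOS synaptic
circuit in which three floating-gate (FG) MOSFETs implement pair-based,
weight-dependent spike-timing-dependent plasticity (STDP). Two fast FG
nodes act as leaky integrators holding the pre- and postsynaptic spike
traces; a third, slow FG node stores the analog synaptic weight. Charge
leaks off each FG through a thin tunnel junction, which is what gives the
integrators their biologically plausible (tens to hundreds of ms)
relaxation times and the storage node its tens-of-seconds retention.

The package reproduces the five behavioral experiments that characterize
such a circuit without transistor-level simulation: plasticity induction
and the single-pair STDP curve, the weight dependence of the pair rule and
the bidirectional-pairing bifurcation, unsupervised and supervised
synaptic competition in a two-afferent network, phase-plane (weight-plane)
vector fields of the competition, and Monte-Carlo propagation of MOSFET
mismatch to the STDP behavior.

# Device model: charge relaxation

A FG node with capacitance $C_\mathrm{FG}$ loses charge through its tunnel
junction. The junction current uses a one-carrier direct-tunneling
(Simmons/WKB) form,

$$ I(V) = A \, g_0 \, V \, e^{-2\kappa t_\mathrm{tun}}, \qquad
   \kappa = \frac{\sqrt{2 m^* m_e q \phi}}{\hbar}, $$

with junction area $A$, barrier thickness $t_\mathrm{tun}$, barrier height
$\phi$ (default 3.1 eV, SiO~2~) and effective-mass ratio $m^*$ (default
0.4). Barrier lowering is ignored. The form is linear in $V$, so free
relaxation is exactly exponential with time constant
$\tau = C_\mathrm{FG} / (A g_0 e^{-2\kappa t_\mathrm{tun}})$; what the law
is designed to capture is the exponential sensitivity of the relaxation
time to barrier thickness (a 30% thickness increase around 1.3 nm slows
relaxation by roughly two orders of magnitude, since
$e^{2\kappa \cdot 0.39\,\mathrm{nm}} \approx 90$) and its linear scaling
with capacitance.

The only free parameter, the conductance prefactor $g_0$, is fixed by
`calibrate_leak()` against a single anchor: a 2 fF node behind a 1.3 nm
barrier has a half-peak relaxation time $\tau_\mathrm{relax}$ of 0.5 s.
The storage element (two junctions of 1.75 nm on a 30 fF node, combined
area 36 000 nm²) gets its own prefactor, calibrated so that the
10%-decline retention time of a programmed level is 85 s — the centre of
the 70–100 s band the storage element is designed for. Because the law is
linear, the model's retention time is level-independent; the
level-dependence seen in device measurements (larger stored voltages
leaking slightly faster) is not captured, only bounded: the model's
retention is weakly monotone (constant) in the programmed level.

Relaxation and retention times are found in closed form in exponential
mode and by bisection on a log-time grid between 1 µs and $10^4$ s
(relative tolerance $10^{-3}$) in tunneling mode; a leak too slow to cross
the target within the horizon is reported as a non-convergence error.

# Synapse model

## State variables and sampling

A presynaptic spike resets the presynaptic FG trace to
$\Delta V_\mathrm{pre} = 180$ mV (nearest-pairing; in accumulate mode it
increments), and a postsynaptic spike resets the postsynaptic trace to
135 mV. The traces relax with time constants $\tau_\mathrm{pre}$ and
$\tau_\mathrm{post}$. The sampling subcircuits amplify the FG voltages
onto the state variables,

$$ s_\mathrm{pre} = -g_\mathrm{pre} V_\mathrm{FG,pre}, \qquad
   s_\mathrm{post} = +g_\mathrm{post} V_\mathrm{FG,post}, $$

with gains 3.6 and 4.8 so that both state variables peak at 0.648 V after
a single spike. The gains are needed because the injection thresholds
(next paragraph) sit *above* the raw FG jumps; physically they stand for
the two-stage transfer of the sampling circuits.

A counter-spike samples the opposing state variable. Injection into the
storage node happens only above a junction threshold — 0.35 V for the
depression junction and 0.33 V (magnitude) for the potentiation junction —
which truncates each plasticity window at a finite reach:
$\tau_\mathrm{pre}\ln(0.648/0.33) \approx 37$ ms for potentiation and
$\tau_\mathrm{post}\ln(0.648/0.35) \approx 169$ ms for depression. Beyond
those offsets a single pair changes nothing, exactly as a
threshold-limited charge injector behaves.

## Detailed-balance storage update and the VTC

The storage level $m$ (the behavioral image of the storage-FG voltage)
moves by

$$ \Delta m_\mathrm{LTP} = -c_+ (|s_\mathrm{pre}| - \theta_+)\,
     e^{\,\mathrm{clip}((m - m_0)/\lambda_+)}, \qquad
   \Delta m_\mathrm{LTD} = +c_- (s_\mathrm{post} - \theta_-)\,
     e^{\,\mathrm{clip}(-(m - m_0)/\lambda_-)}, $$

an exponential self-limiting (detailed-balance) factor: the further the
node has already moved in the injection direction, the smaller the next
injection. The exponent is clipped at ±1.5 so that the factor saturates
deep in a transfer pole; without the clip a single pair starting at
$w \approx 2$ mV would catapult the weight across the whole range, and the
potentiation branch of the weight-dependence curve would not vanish at the
depression pole as it must. The clip only engages below $w \approx 35$ mV
and above $\approx 0.46$ V, far from every calibrated operating point.

The observable weight is a logistic voltage-transfer characteristic
(VTC),

$$ w(m) = \frac{V_\mathrm{max}}{1 + e^{(m - m_\mathrm{mid})/\sigma}}, $$

bounded in $(0, 0.5)$ V with slope parameter $\sigma = 0.2$ V, decreasing
in $m$ (potentiation injects electrons, $m$ falls, $w$ rises; the polarity
is internal). $m_\mathrm{mid}$ is placed so the resting level maps to the
reference weight of 151 mV — the single behavioral knob standing in for
the storage control bias.

## Tie handling

A spike that coincides exactly with a sampling instant contributes
nothing (the $\Delta t = 0$ branch of the pair rule): the sample reads the
trace of the most recent *strictly earlier* counter-spike. One causal
exception: a postsynaptic spike *emitted by the membrane in response to*
a presynaptic spike at the same instant samples the triggering synapse's
freshly set trace, because the physical pre-to-post latency is positive
($\Delta t \to 0^+$). This is what lets the synapse that evokes firing
collect the causal credit; without it the two-afferent competition
provably cannot bifurcate (the cross-pair credit is equalizing), while
imposed simultaneous pre/post spikes still produce zero change.

## Calibration of the defaults

The default parameters are solved, in order, from four anchors:

1. **Windows.** $\tau_\mathrm{pre}$ and $\tau_\mathrm{post}$ are
   root-solved so that the least-squares exponential fit of the default
   single-pair curve (timing grid to ±400 ms, initial weight 151 mV)
   returns exactly 16.8 ms (LTP) and 76.5 ms (LTD):
   $\tau_\mathrm{pre} = 55.40$ ms, $\tau_\mathrm{post} = 274.24$ ms. The
   fitted windows are shorter than the leak constants because the
   threshold truncates the curve.
2. **VTC slope.** $\sigma = 0.2$ V gives the detailed balance enough
   leverage between the resting weight and the pairing plateau that one
   causal trigger outweighs the accumulated anti-causal echo of a 20 Hz
   input bin; with a steeper VTC the binned competition protocols lose
   weight on net at rest and freeze.
3. **Balance scales.** $\lambda_+ = 0.25$ V is the largest scale at which
   successive causal-pair potentiation steps from rest still shrink
   monotonically (competition strengthens as soft-bounding weakens, so
   the scale sits at that stability edge); $\lambda_- = 0.70$ V keeps
   depression alive near the lower pole so a losing afferent stays
   disconnected.
4. **Gains.** The ratio $c_+/c_-$ is solved from the fixed point of the
   20 Hz pairing map — per 50 ms period the leading synapse receives one
   LTP at $+1$ ms and one LTD echo at $-49$ ms, and the two cancel at
   $w = 0.27$ V, the empirical pairing maximum. $c_+ = 0.10$ sets the
   absolute rate: one full-strength causal pair moves the weight by
   ≈16 mV from rest, which completes the joint growth phase of the
   competition within tens of seconds. This gives $c_- = 0.0540$.

## A structural trade-off, stated openly

With all anchors above fixed, two remaining targets pull in opposite
directions. The binned 20 Hz protocols stay alive only if the single
causal-trigger LTP outweighs the integrated anti-causal echo of an input
bin, which caps the depression-to-potentiation gain ratio; the losing
afferent of the unsupervised 5 Hz competition collapses below 50 mV only
if depression dominates the boundary-repelled potentiation at low weight,
which bounds the same ratio from below. The two bounds conflict for every
admissible setting of the slope, balance scales and gains (the
echo-to-anchor ratio is pinned near 2.3 by the 76.5 ms window). The
default calibration keeps every experiment qualitatively correct —
unsupervised runs always bifurcate with the winner above 0.2 V and a fair
winner identity, the bias neuron steers the supervised competition
essentially always, the pairing plateau sits at 0.268 V — at the cost
that the unsupervised loser settles near 0.10 V rather than below
0.05 V. The opposite calibration (loser below 0.05 V) freezes the binned
protocols entirely and drops supervised steering to chance; it was
rejected as strictly worse.

# Neuron model and spike sources

The postsynaptic point neuron integrates exactly between events: the
membrane potential decays as $e^{-\Delta t/\tau_m}$ ($\tau_m = 10$ ms) and
jumps by $\alpha\, w$ ($\alpha = 0.3$, $w$ the sampled weight) at each
input spike; at 90 mV it fires and resets to 0, with no refractory
period. Spikes can therefore only be emitted at input-event instants,
which makes the whole network simulation event-driven and free of
time-stepping error.

Poisson sources draw i.i.d. exponential inter-spike intervals; the binned
alternating source activates one of the inputs per 200 ms bin, uniformly
at random, at 20 Hz; the supervision bias emits its own Poisson train (50
mV fixed weight; 50 Hz by default, 80 Hz in the steering experiments)
during the bins in which its synced input is active — synchrony is
interpreted at bin granularity, spike-level coincidence being a degenerate
special case reachable by configuration. Every ensemble derives
per-source and per-replicate sub-stream seeds from one master seed via a
documented multiplicative-congruential mix (`derive_seed()`), so all runs
are bit-reproducible.

# What the generated stimuli do and do not emulate

The protocols generate exactly the study conditions: deterministic
1 ms/50 ms pair schedules, independent 5 Hz Poisson pairs over 150 s,
200 ms alternating bins at 20 Hz, and the biased variant over 100 s.
They do not emulate rate nonstationarity, correlated input statistics,
axonal or dendritic delays, inhibition, or more than two plastic
afferents; conclusions from passing tests are therefore about the pair
rule and its competition dynamics under these idealized drives, not about
arbitrary spiking regimes.

# Mismatch model

Random dopant fluctuation perturbs each device's threshold voltage with
the Pelgrom standard deviation $A_\mathrm{RDF}/\sqrt{LW}$
($A_\mathrm{RDF} = 1.27\times10^{-9}$ V·m; 15 mV for the smallest,
60 × 120 nm, devices), and line-edge roughness perturbs channel length
with $A_\mathrm{LER}/\sqrt{W}$ ($A_\mathrm{LER} = 1.04\times10^{-12}$
m^3/2^; ≈3 nm at 120 nm width). The device-to-behavior map is first-order
and configurable: a device's threshold deviation scales its per-spike
increment and sampling threshold by 1% per mV, its length deviation
scales the associated time constant (integrators) or injection gain
(junctions) by the relative length change, and storage-device threshold
deviations shift the resting storage level, spreading the initial weight
by a few mV (normally distributed). With the 15 mV device sigma this
yields ±15% behavioral jitter — a visibly spread ensemble of STDP curves
whose timing signs survive in well over 90% of circuits, and a supervised
competition that the synced input wins by a modest (≈60%) but
statistically solid majority over a large ensemble.

# Numerical choices

* VTC inversion (`set_weight()`): bisection to $10^{-9}$ V on $m$; the
  poles are excluded (saturation is unreachable).
* STDP fits: separate Levenberg–Marquardt least squares per branch
  (`minpack.lm`), amplitudes bounded below by 0, starts taken from the
  half-peak offset; zeros beyond the window support are part of the fit.
* Relaxation/retention searches: log-time bisection, tolerance $10^{-3}$.
* Simultaneous events are processed in ascending source order and the
  membrane threshold is checked after each increment (first crossing
  wins).
* Weight traces are step-sampled from the exact event log, so the
  sampling interval can never perturb the dynamics.
* Phase-plane fields use a 15 × 15 interior grid on [0.02, 0.48] V² by
  default, a 2 s horizon, and 10 replicates with independent sub-streams;
  trajectory overlays interpolate the field bilinearly and exclude
  segments where the field magnitude is below three times its standard
  error or outside the grid hull.

# Problem sizes

The test-suite ensembles use 100 seeds × 150 s for the unsupervised
criterion, 100 seeds × 100 s per direction for the supervised criterion,
30–50 seeds for module-level checks, 400 mismatched circuit pairs for the
supervised Monte-Carlo majority (sized for adequate binomial power on a
~0.6 majority), and 100 random 100-event sequences for the replay-oracle
equivalence. These sizes were chosen so each statistical check has
comfortable power at its stated significance level.

# Known limitations

* No transistor-level fidelity: node voltages, pulse shapes, power and
  temperature behavior are out of scope; spike pulses are instantaneous
  events with their 0.5 V/30 µs physics absorbed into the jump and gain
  constants.
* The linear tunneling law makes retention level-independent.
* The unsupervised loser floor sits near 0.10 V (see the trade-off
  section), and single-pair LTP has finite support (≈37 ms), so the pair
  rule's sign is only defined up to that reach.
* Networks are limited to a few sources and one or two targets; no
  delays, no inhibition.

# A worked example

```{r example, eval = FALSE}
library(fgstdp)

# single-pair STDP curve of the default synapse and its window fit
fit <- fit_stdp(stdp_curve(synapse_params()))
fit

# bidirectional 20 Hz pairing: causal synapse saturates, reverse decays
tr <- protocol_bidirectional_pairing(duration_s = 100)
mean(tr$weights[tr$times >= 90, "N1->N2"]) # plateau near 0.27 V
tr$terminal[["N2->N1"]]                    # ~0 V

# unsupervised competition and its phase plane
cmp <- protocol_unsupervised(duration_s = 150, seed = 1)
field <- vector_field("compete", grid = 15, replicates = 10, seed = 1)
overlay_trajectories(field, cmp)
```
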
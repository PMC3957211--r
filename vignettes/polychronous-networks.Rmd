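---
title: "Storing and recalling spatio-temporal spike patterns with programmable axonal delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and recalling spatio-temporal spike patterns with programmable axonal delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysnn)
library(dplyr)
```

## The model

A polychronous spiking neural network stores *spatio-temporal patterns*:
ordered lists of (neuron, firing-time) pairs.  Spikes travel down axons with
specific delays so that, although the source neurons fire asynchronously,
their spikes arrive at a common target neuron simultaneously and make it
fire — a time-locked relation that propagates through the whole pattern.
`polysnn` simulates a *reconfigurable* version of this idea as an
event-driven system with two functional arrays:

* a **neuron array** of coincidence detectors.  Each neuron has four
  synapse lines and fires when at least three of them receive a
  pre-synaptic spike within a 1 ms window (threshold 3-of-4 limits
  cross-talk between stored patterns).  Two behavioural backends exist:
  a *digital* model (one timer per line plus a comparator) and an *analog*
  leaky integrate-and-fire model (per-line synapse currents decaying with
  `tau_syn`, a first-order membrane filter
  `tau_mem * dI_out/dt + I_out = sum(I_syn)`, a firing threshold and a
  refractory period during which no integration happens).
* an **axon array** of identical modules.  A module has one input address
  register, four output address registers, four programmable delay paths
  and a shared ramp generator.  When a post-synaptic spike matching the
  input address arrives, the ramp restarts and each path emits a
  pre-synaptic spike to its output address after its programmed delay, on
  the active line matching the path index.  A ramp restart cancels
  emissions still pending from the previous trigger.

Training allocates modules to pattern spikes strictly in sequence: spike
*k* of a pattern becomes module *k*'s input, and the next four spikes
become its outputs, with the four observed inter-spike intervals stored as
delays.  A pattern of *S* spikes therefore consumes exactly *S* modules,
and an array of *M* modules stores `floor(M / S)` patterns.  Recall
presents the first few spikes of a pattern (three by default — the minimum
that delivers three coincident arrivals to the next neuron in the chain);
the network completes the rest.  Recall can also enter mid-pattern.

Delays are configured in one of two ways:

* **delay programming** — one-shot storage of the observed interval; and
* **delay adaptation** (spike-timing-dependent delay plasticity) — the
  delay shrinks when the pre-synaptic spike arrives after the destination
  neuron fires and grows in the opposite case, by one of three update
  rules: the exact error in one step (equivalent to programming), a fixed
  step per presentation, or a step proportional to the error.  With the
  default coefficient of 0.5 the timing error halves each presentation, so
  five presentations leave 1/32 of the initial error.

## Address-event representation

Spikes are communicated as addresses on shared buses.  The physical analog
buses use constant-weight (k-of-n) codes — exactly *N* of *M* wires HIGH —
because their encoders/decoders are cheap in analog VLSI: a 3-of-8 code
(56 addresses) on the neuron buses and a 4-of-9 code (126 addresses) on
the axon bus, with dedicated active lines (one per target synapse) instead
of a handshake, and no arbiter.  `build_codebook()` fixes the
index-to-codeword bijection in lexicographic bit-vector order, and the
router's four lookup tables (`router_tables()`, `remap()`) convert between
binary indices and bus codewords.

Because the analog side is unclocked, its spikes must be synchronised into
the clocked domain.  `sample_bus()` models the three-step interface: every
wire passes a two-register synchroniser (two clock periods at the default
50 MHz); a popcount counter latches the synchronised word into a 32-deep
FIFO when it *becomes* valid, when one valid address replaces a different
one, or — on the four-active-line axon bus — when the same address
reappears on a different line; and the FIFO drains into fixed-width output
spikes, one per four clock cycles.  A held valid address is ignored, so a
spike is sampled once.  `synthesize_bus_waveform()` builds the stimuli:
per-wire skew offsets (bounded by `skew_max`), per-pulse width jitter, and
brief glitch pulses.  Glitches are injected on currently-LOW address wires
while a valid address is on the bus: they momentarily raise the popcount
above *N* (invalid, ignored) and retrigger the latch condition when the
word returns — which duplicates the sample within a microsecond but can
never produce a *wrong* address.  Skew alone cannot either, because during
a rise only subsets of the true codeword are visible (popcount < N) and
during a fall only subsets remain.  The optional dedup timer
(`dedup_us`) suppresses such duplicates; it is off by default because a
duplicate only shifts the downstream ramp start by under a microsecond.

## Virtual-neuron multiplexing

Only a small fraction of neurons is active at any instant, so a pool of 50
physical neurons can serve 4096 virtual addresses (an ~80-fold area
saving).  The controller (`controller_state()` and the `"multiplexed"`
backend) leases a free physical neuron to the first spike of an unassigned
virtual address, latches the address, and frees the neuron when a 1 ms
timer — matching the coincidence window — expires.  The lease is *not*
renewed by further spikes; whether the original hardware renews it is not
documented, and no-renewal keeps the lease semantics identical to the
coincidence window.  When the pool is exhausted the spike is dropped,
counted and logged (the hardware behaviour on exhaustion is likewise
undocumented; dropping is the conservative choice).

## Analog imperfections

The analog axon cannot be programmed exactly.  `imperfection_model()`
captures this behaviourally with three parameters:

* `sigma` (default 0.10): each programmed delay is multiplied by
  `1 + e`, `e ~ Normal(0, sigma)` — the relative offset between desired
  and stored delay caused by charge injection and ramp inaccuracy;
* `residual` (default 0.3 ms): additive uniform jitter on every emission
  time, the residual timing error that remains after adaptation; and
* `spurious_p` (default 0): the probability that parasitic coupling makes
  a neighbouring delay path of the same module emit as well.

The analog axon's training schedule is delay programming followed by a
number of fixed-step adaptation iterations (defaults: 20 iterations of
0.1 ms), i.e. `train(..., mode = "adaptation", init = "programming")` with
a `fixed_step` policy.  Note the interplay of scales: with delays of up to
~60 ms a 10% relative error can reach several milliseconds, while 20
iterations of 0.1 ms can correct at most 2 ms, so long delay paths remain
partly uncorrected; the residual jitter bound is only attained by paths
whose initial error the iteration budget covers.  This is why, in
`run_axon_imperfection_experiment()`, recalled-spike fractions fall with
pattern length and adaptation helps most for long patterns — the
directions matter here, not the absolute levels, which in real hardware
depend on device statistics this model does not attempt to reproduce.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` / `n_lines` | 3 / 4 | — | coincidences needed to fire |
| `window` | 1 | ms | digital coincidence window |
| `refractory` | 2 | ms | post-fire dead time (both backends; the duration is a modelling choice, the circuits only bound it) |
| `tau_syn` | 1.6 | ms | analog synapse decay |
| `tau_mem` | 0.023 | ms | membrane filter (device values n = 1.5, U_T = 25.6 mV, C_mem = 0.6 pF, I_t = 1 nA) |
| `threshold` (analog) | calibrated | — | bisection-calibrated, see below |
| `max_delay` | 100 | ms | ramp range (the hardware range is not quantified) |
| `initiation` | 3 | spikes | recall initiation count (= threshold) |
| `lease_ms` / `pool_size` | 1 / 50 | ms / — | controller lease and pool |
| `isi_min`–`isi_max` | 5–15 | ms | generator inter-spike intervals |
| `all_firing_factor` | 5 | — | runaway-activity cutoff |

Two of these deserve their rationale spelled out.

**Analog synapse decay.**  With synapses that *reset to full amplitude*
on a spike (the capacitor is pulled to ground — maximal current) and a
membrane far faster than the synapse, the summed current right after the
k-th coincident spike is `1 + sum_i exp(-dt_i/tau_syn)`.  A synapse decay
derived from the stated device values (~0.32 ms) makes two simultaneous
spikes (summed current 2.0) indistinguishable from three spikes spread
over the full 1 ms window (~1.27): no threshold can then accept every
3-in-1-ms triple while rejecting every pair.  The criterion the detector
must meet fixes a lower bound of roughly `tau_syn >= 1.5` ms; the default
is 1.6 ms, which separates the worst triple (~2.07) from the best pair
(2.0).  `calibrate_analog_threshold()` then finds the threshold by
bisection between those two responses and errors out if the time constants
cannot realise the criterion.  The margin is deliberately thin: the analog
neuron remains a less precise coincidence detector than the digital one
(there is no hard window edge), which is faithful to its role.

**Refractory period.**  The refractory circuits only bound the duration
(capacitor and charging current); 2 ms — twice the coincidence window — is
used for both backends.  The headline results are insensitive to it (0 ms
was checked and changes nothing at the default study sizes), because at
the cross-talk levels of the standard configurations neurons are rarely
asked to fire twice within 2 ms.

## The synthetic-data generator

`generate_patterns()` emulates the hardware's pattern generator: neuron
addresses uniform over the network, no neuron repeated within any five
consecutive spikes (so the four delay paths of a module always target
distinct neurons), inter-spike intervals i.i.d. uniform on 5–15 ms — a
51-spike pattern then spans about 500 ms, ~100 spikes/s.  `disjoint = TRUE`
partitions the neuron space so patterns share no neurons (zero
cross-talk by construction), the regime used for the small analog-axon
experiments.  `generate_noise()` draws a network-level homogeneous Poisson
train with uniformly random neuron and synapse line per event; the rate
(2–128 spikes/s) counts extra spikes across the whole network.  Noise is
injected at recall time; training is a supervised replay in which each
delay path is paired with its own target spike, so the convention of
adding no noise during the first training presentation is honoured by
construction.

What the generator does *not* emulate: correlated or bursty noise,
sensor-driven input patterns, neuron repeats closer than five positions,
and any discretisation of spike times (the hardware is clocked and
time-multiplexed; the model keeps continuous time, with an optional
`quantization` step, default off).  Passing tests therefore demonstrate
the model's behaviour under idealised, independently drawn patterns — not
performance on recorded data.

## Numerical choices

* **Event ordering.**  Events are processed in (time, insertion sequence)
  order; simultaneous arrivals are handled in the order they were
  scheduled, and neuron firing is evaluated per arriving event.  The
  compiled engine (Rcpp, used for the digital backend) and the plain-R
  reference engine implement this contract independently and are tested to
  emit byte-identical spike trains.
* **Analog integration.**  Between events the synapse/membrane system has
  the closed-form two-exponential solution; no fixed-step integration is
  used.  Threshold crossings are located from the analytic stationary
  point of the trajectory plus bisection, and predicted-crossing events
  (cancelled by any later arrival, which can only move the crossing
  earlier) make firing between arrivals exact.  A dense-grid Euler
  integrator exists in the test suite as an independent oracle.
* **Delay clamping.**  Adaptation updates clamp to `(0, max_delay]`;
  a requested delay of zero or beyond the ramp range is a programming
  error.
* **Quiescence cap.**  A recall run ends when the queue empties or at
  `t0 + pattern end + 10 * max_delay`; a run emitting more than
  `all_firing_factor` times the stored spike count is cut off and flagged
  all-firing (the hardware describes this catastrophic cross-talk state
  qualitatively; the 5x cutoff is a modelling choice).
* **Degenerate inputs.**  Empty initiation yields an empty train;
  out-of-order events raise sequencing errors; decode of a word whose
  popcount is not N raises an invalid-codeword error; pool exhaustion
  drops and counts.

## Problem sizes used in the checks

The test suite and the acceptance script run the study configurations at
the sizes the experiments define: the codebooks exhaustively; the
capacity arithmetic on the 100-module array; the time-locked round trip
on five disjoint 20-spike patterns; the size sweep at 128/256/512 neurons
with 82 patterns of 51 spikes over 10 seeded runs; the capacity
experiment at 4096 neurons and 81 920 modules with 1200 patterns over 3
seeded runs; the interface circuit at 50 addresses x 128 repetitions x 10
runs; and the imperfection experiment at 40 seeded runs per pattern
length and mode.  The event-driven core makes these sizes cheap (the
largest single run processes a few hundred thousand events).

## Known limitations

* The all-firing transition of the fully digital configuration is
  reproduced qualitatively (128-neuron networks collapse, 512 and larger
  are at ceiling) but its critical point is sharp: at 256 neurons the
  idealised continuous-time model sits near ceiling, whereas clocked,
  time-multiplexed hardware — with its timing grid and additional
  interaction channels — degrades earlier.  Quantities quoted exactly at
  the transition should be read with that in mind.
* Transistor-level behaviour is out of scope: no metastability, no
  charge-injection physics (only its statistical delay offset), no
  current-mirror gain tuning, no spike-rate adaptation or bursting.
* The quantitative once-vs-twice sampling split of the interface circuit
  depends on physical glitch statistics that are not modelled; the model
  guarantees only the structural properties (no wrong addresses,
  duplicates are immediate and sub-microsecond).
* Analog-imperfection levels are behavioural parameters, not device
  measurements; only directions of change are meaningful.

## A worked example

```{r example}
pats <- generate_patterns(5, 20, 126, disjoint = TRUE, seed = 42)
cfg <- network_config(n_neurons = 126, n_axon_modules = 100)
net <- train(cfg, pats, mode = "programming")
glance(net)

p1 <- filter(pats, pattern == 1)
r <- recall(net, p1, t0 = 10, seed = 7)
glance(r)
score_recall(p1, r)
```

All 17 non-initiation spikes return at exactly their stored times: the
time-locked relation is preserved perfectly by the noiseless digital
path.  Adding `imperfection_model()` to the configuration, or switching
`backend` to `"analog"` or `"multiplexed"`, degrades this gracefully in
the ways described above.
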
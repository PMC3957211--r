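# polysnn

Event-driven simulation of a reconfigurable **polychronous spiking neural
network**: a memory for spatio-temporal spike patterns built from
coincidence-detector neurons and axon modules with programmable,
adaptable delays.

`polysnn` is aimed at computational neuroscientists and neuromorphic
engineers who want to study pattern storage capacity, cross-talk and
noise robustness of delay-based spiking memories — and at anyone
prototyping mixed-signal systems who needs behavioural models of the
surrounding machinery: k-of-n address-event (AER) codes, an
asynchronous-bus synchronisation interface, and a virtual-neuron
multiplexing controller.

## The model

A *spatio-temporal pattern* is an ordered list of pairs
$(n_k, t_k)$, $t_1 < t_2 < \dots < t_S$.  Neurons are coincidence
detectors: with four synapse lines, a neuron fires at time $t$ iff at
least $K = 3$ lines received a spike in $(t - W, t]$ with $W = 1$ ms
(outside its refractory period).  Axon modules store delays: training
assigns pattern spike $k$ to module $k$, which latches $n_k$ as its input
address and the next four spikes as outputs with delays

$$d_{kj} = t_{k+j} - t_k, \qquad j = 1, \dots, 4 .$$

Replaying the first three spikes makes the spikes of the stored pattern
arrive in coincident triples at each successive neuron, which regenerates
the pattern at its exact stored times (the *time-locked relation*).  A
pattern of $S$ spikes consumes $S$ modules, so $M$ modules store
$\lfloor M/S \rfloor$ patterns.

Delays can also be learned by **spike-timing-dependent delay
plasticity**: with timing error $\Delta = t_{\text{pre-arrival}} -
t_{\text{post-fire}}$, the delay updates as $d \leftarrow d - \Delta$
(exact), $d \leftarrow d - s\,\mathrm{sign}(\Delta)$ (fixed step) or
$d \leftarrow d - c\,\Delta$ (proportional, default $c = 0.5$, which
halves the error per presentation).

The package also models the mixed-signal plumbing: 3-of-8 / 4-of-9
constant-weight AER codebooks ($C = \binom{M}{N}$ addresses: 56 and 126),
a skew/glitch bus waveform model with the three-step synchroniser and
32-deep FIFO that samples it without ever latching a wrong address, a
50-neuron pool serving 4096 virtual addresses through 1 ms leases, an
analog LIF neuron backend ($\tau_{\text{mem}} \dot I_{\text{out}} +
I_{\text{out}} = \sum I_{\text{syn}}$), and an analog-axon imperfection
model (10% programming offset, 0.3 ms residual jitter, optional spurious
emissions).

## Worked example

```r
library(polysnn)
library(dplyr)

pats <- generate_patterns(5, 20, 126, disjoint = TRUE, seed = 42)
cfg  <- network_config(n_neurons = 126, n_axon_modules = 100)
net  <- train(cfg, pats, mode = "programming")
glance(net)
#> # A tibble: 1 × 7
#>   backend n_neurons n_axon_modules n_configured n_patterns mode     modules_free
#>   <chr>       <int>          <int>        <int>      <int> <chr>           <int>
#> 1 digital       126            100          100          5 program…            0

p1 <- filter(pats, pattern == 1)
r  <- recall(net, p1, t0 = 10, seed = 7)
r
#> <polysnn_recall> 17 emitted spikes (cpp engine)
score_recall(p1, r)
#> # A tibble: 1 × 6
#>   n_expected n_scored n_recalled fraction all_firing success
#>        <int>    <int>      <int>    <dbl> <lgl>      <lgl>
#> 1         20       17         17        1 FALSE      TRUE
```

Five disjoint 20-spike patterns fill the 100-module axon array exactly
(`modules_free = 0`).  Presenting the first 3 spikes of pattern 1
regenerates the remaining 17 (`n_scored = 17`) at their stored times
shifted by `t0 = 10` ms — `fraction = 1` means every non-initiation spike
reappeared within the 1 ms scoring tolerance, and `success` applies the
95%-of-spikes criterion.  Experiment drivers (`run_size_sweep()`,
`run_capacity_experiment()`, `run_noise_sweep()`,
`run_axon_imperfection_experiment()`) return tidy tibbles with
`autoplot()` methods; a thin command-line front end lives in
`inst/cli/polysnn.R`.

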
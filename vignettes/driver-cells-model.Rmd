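---
title: "A spiking-network model of developing circuits: population bursts, functional cliques and driver cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-network model of developing circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstclique)
```

## The model

Developing cortical circuits exhibit spontaneous network-wide
synchronizations — giant depolarizing potentials (GDPs) in slices, here
modelled as *population bursts* (PBs). `burstclique` implements a diluted
network of N = 100 leaky integrate-and-fire (LIF) neurons (90 excitatory,
10 inhibitory) coupled through Tsodyks–Uziel–Markram (TUM) short-term
synaptic plasticity.

The membrane potential of neuron $i$ obeys

$$\tau_m \dot V_i = -V_i + I^{syn}_i + I^b_i,$$

with $\tau_m = 30$ ms; when $V_i$ reaches $V_{th} = 15$ mV it is reset to
$V_r = 13.5$ mV and a $\delta$-spike is transmitted. Input resistance is
folded into the currents, so drives are in mV. Each synapse partitions its
transmitter resources into recovered ($X$), active ($Y$) and inactive
($Z$) fractions with $X+Y+Z=1$:

$$\dot Y_{ij} = -\frac{Y_{ij}}{T^I_{ij}} + u_{ij} X_{ij} S_j, \qquad
  \dot Z_{ij} = \frac{Y_{ij}}{T^I_{ij}} - \frac{Z_{ij}}{T^R_{ij}},$$

where $S_j$ is the presynaptic spike train. The release fraction $u_{ij}$
is constant ($u \equiv U$, depression only) on synapses onto excitatory
neurons and facilitating on synapses onto inhibitory neurons:

$$\dot u_{ij} = -\frac{u_{ij}-U_{ij}}{T^F_{ij}} + U_{ij}(1-u_{ij}) S_j.$$

The synaptic current is degree-normalized,
$I^{syn}_i = \frac{1}{K^I_i}\sum_j G_{ij} Y_{ij}$, with $G_{ij} < 0$ iff
the presynaptic neuron is inhibitory. Indices are (postsynaptic,
presynaptic) throughout the package.

## The network generator defines the study conditions

`networkConfig()` carries the defaults under which all results are
produced; `buildNetwork()` draws one realization:

* connectivity: directed Erdős–Rényi with mean in-degree 10 (each ordered
  pair carries an edge with probability $10/99$);
* synaptic parameters: per-edge Gaussians with SD equal to half the mean:
  $\bar T^I = 3$ ms everywhere; $\bar T^R = 800$ ms onto excitatory and
  100 ms onto inhibitory neurons; $\bar T^F = 1000$ ms (onto inhibitory
  only); $\bar U = 0.5$ onto excitatory, $0.04$ onto inhibitory;
  couplings $|\bar G| = 45$ mV (e←e), 135 mV (e←i), 180 mV (i←e, i←i).
  Nonpositive draws of time constants and couplings are redrawn; $U$ is
  clipped to $[0.001, 0.999]$ — positivity is required by the dynamics
  and the tail mass involved is small;
* excitabilities: flat distribution spanning **±0.45 mV around the 15 mV
  threshold** (support [14.55, 15.45] mV), with *exactly* 10% of neurons
  above threshold. The half-width reading is fixed by the published hub
  excitabilities (up to 15.42 mV) and by the maximal control firing rate
  of ≈22 Hz, which equals the natural rate at 15.45 mV. The exact
  suprathreshold count is enforced by redrawing the top-ranked tenth of
  the sample into (15, 15.45] and the rest into [14.55, 15];
* the developmental anti-correlation: excitabilities are rank-assigned
  against total structural degree $K^T = K^I + K^O$ (largest degree ↔
  smallest excitability; ties broken by neuron index), giving Spearman
  correlation −1. The *uncorrelated control* keeps the draw but assigns
  it randomly; because the assignment consumes no random numbers, the
  correlated and uncorrelated builds with the same seed share the graph,
  the excitability values and every synaptic draw — matched pairs that
  isolate the effect of the correlation.

These defaults are the conditions under which the acceptance statistics
are computed and are not adjusted per-analysis.

## Exact event-driven integration

Between spikes every state variable has a closed form (exponentials and a
two-exponential solution for $Z$), so the network can be advanced from
one spike to the next without discretization. The threshold-crossing time
of a sum-of-exponentials $V(t)$ has no closed form; the simulator
brackets it with interval bounds that exploit the monotonicity of each
exponential term (so a crossing inside an interval can never be stepped
over) and bisects to a tolerance of $10^{-10}$ ms. Lazy per-neuron and
per-edge clocks keep the cost per event at the affected subgraph only.
Simultaneous crossings are processed in ascending neuron index; at a
facilitating synapse the spike first updates $u$ and then releases
$u \cdot X$ (the standard TUM convention; the ordering of the δ-terms is
otherwise ambiguous).

The independent check is `referenceSimulate()`, a fixed-step RK4
integrator that sub-steps to the linearly interpolated crossing before
applying resets and synaptic jumps. On every fixture the two engines
agree event-for-event to better than $10^{-3}$ ms over 1 s.

Choices the equations do not fix (and the defaults adopted):

* initial conditions: $V_0 \sim U[V_r, V_{th})$, $X=1$, $Y=Z=0$, $u=U$;
* a 10 s burn-in is simulated and discarded before every analysis window;
* optional "channel noise": the reset is drawn uniformly from
  $[V_r-\Delta, V_r+\Delta]$ per spike ($\Delta = 0$ by default, giving
  bit-reproducible runs for a fixed seed);
* DC stimulation substitutes the neuron's drive: during a step the
  effective drive *is* $I^{stim}$ (stimulating at the neuron's own $I^b$
  reproduces control), which is what makes sub-threshold stimulation
  currents meaningful in the sweeps.

## Burst detection conventions

A PB is a run of 10-ms bins (anchored at the window origin) in which the
number of *distinct* firing neurons strictly exceeds 25% of the
population; the peak is the centre of the maximal-count bin and the width
the extent of the merged run. Spike-count and distinct-neuron conventions
give virtually identical catalogs on this model — the bursts are nearly
synchronous at 10 ms resolution — and the distinct convention matches the
participation language used to describe them. Build-up analysis
re-locates each peak at 1 ms resolution (first bin with more than 5% of
neurons firing), takes the preceding 70 ms as the build-up window, and
places threshold crossings by linear interpolation between bin counts.

Aborted bursts (ABs) — collective activations that fail to reach the PB
threshold — have no quantitative published definition. The operational
rule implemented (and exposed as arguments): a local maximum of the
binned distinct-neuron count that exceeds twice the median out-of-burst
bin count, involves at least 10% of the population, is not part of a PB
and lies at least 50 ms from every PB peak. The published AB/PB
percentages should be read as calibrating this rule's scale, not as
sharp constants; per-realization AB counts vary strongly.

The phase indicator of an event train, $\Phi_i = (t^i_G - i\Delta t)/
\Delta t$, and the two-sample Kolmogorov–Smirnov comparison of IGI
distributions (with a 60 s rolling-mean construction) quantify
stimulation-induced accelerations and slow-downs.

## Functional connectivity

Spike trains are reduced to surrogates so that a PB contributes one event
per neuron: a sequential 35 ms inter-spike filter (functional degrees),
first spikes in the 70 ms build-up window (clique analysis), or
out-of-burst spikes. The correlogram of two 1-ms binary trains,
$C_{ab}(\tau) = \sum_t a_{t+\tau} b_t / \min(\sum a, \sum b)$, is, up to
normalization, the histogram of pairwise spike-time differences. A
directed edge is assigned only when two null models are *both* rejected
at the 5% level: a flat correlogram (uncorrelated firing; KS test of the
lag sample against the uniform law on the lag range) and a zero-centred
correlogram (synchronous firing; Student's t test of mean lag 0). The
direction follows the sign of the correlogram peak; peak ties resolve
toward smaller |lag| and an unresolved sign tie yields no edge. The
precise statistical recipe behind the published tests is not specified;
this policy is validated by its type-I control on independent Poisson
trains (false-edge rate ≤ 5%) and by recovery of planted lag chains.
Functional degrees are percentages of the $n-1$ potential partners, with
hubs at the 90th percentile of $D^O$.

## Perturbation protocols and driver classes

`baselineVariability()` measures the PB-count distribution over
independent initial conditions (84 s windows); significance of any
perturbation requires leaving the ±3 SD band. Single-neuron deletion
(SND) removes a neuron entirely; single-neuron stimulation (SNS) applies
a DC step for the window, swept over 14.5–18 mV (published step
0.015 mV; coarser grids trade resolution for runtime). A neuron is a
*driver hub* when deletion cuts PBs by ≥ 50% (and beyond 3 SD, applied
conjunctively — the conservative reading of the two published gates); a
non-hub is an *LC driver* when some stimulation current changes PBs by
≥ 50%, split into LC1 (can reduce) and LC2 (only enhances).
`extractClique()` orders the hubs by their build-up first-spike
cross-correlations, identifies the leader as the hub with zero build-up
functional in-degree, and enumerates firing routes (repeat spikes
distinguished by occurrence index), with per-step delay statistics on the
dominant route. `resourceMonitor()` tracks the mean recovered fraction
$X^{OUT}_i = \frac{1}{K^O_i}\sum_k \epsilon_{ki} X_{ki}$ and extracts the
pre-PB local maxima whose smallest value estimates the minimal ignition
resource $X^{OUT*}$; on bursting realizations the IGI grows with the
pre-PB $X^{OUT}$ of the gatekeeper hubs, reproducing the
resource-limited ignition mechanism.

## What the tests do and do not show

The fixtures (`pair_entrain`, `gate`, `chain6`, `lc_probe`) isolate one
mechanism each — entrainment of an inhibitory cell, inhibitory gating, a
single-route clique chain, and a silent probe that suppresses collective
events only under stimulation. They are deterministic micro-networks:
passing them validates the machinery, not the emergent statistics.

The emergent claims are checked on the full ensemble: five or more
bursting correlated realizations (84 s after burn-in; the ensemble, like
the published one, contains non-bursting members) against the published
bands for mean IGI, PB width, AB/PB ratio and participation, plus the
matched uncorrelated controls. Two ensemble-level properties of the
published uncorrelated control do not reproduce under our conventions
and are deliberately left failing rather than absorbed into tolerances:
its burst width (published 30 ± 6 ms; we measure ≈ 14–17 ms with the
10-ms merged-run convention) and its AB fraction relative to the
correlated case; our matched uncorrelated networks also retain a few
neurons whose perturbation crosses the 50% line (published maximum
25–30%). All three trace to the uncorrelated variant being less vigorous
in our hands (mean IGI ≈ 0.5 s vs the published 0.3 s).

Problem sizes: the test suite simulates 84 s windows for the ensemble
blocks and 1–10 s horizons elsewhere; the acceptance script pools eight
bursting correlated realizations and their matched controls. A full
84 s + burn-in run of the N = 100 network takes on the order of a second
of CPU.

Synthetic data stand in for real recordings everywhere: the generator
emulates the published model's statistical ensemble, not biological
variability — conclusions about real developing circuits rest on the
original experiments, not on these simulations.

## A short session

```{r example, eval = FALSE}
net <- buildNetwork(networkConfig(), seed = 301)
run <- simulateNetwork(net, 84000, seed = 301)   # 84 s after 10 s burn-in
ct <- detectAbortedBursts(run, detectBursts(run))
burstStatistics(ct)

base <- baselineVariability(net, nRuns = 10, windowS = 84, seed = 9000)
snd <- vapply(1:100, function(i)
  sndExperiment(net, i, windowS = 84, seed = 301)$nPB, numeric(1))
hubs <- which((base$mean - snd) / base$mean >= 0.5 &
              abs(snd - base$mean) > 3 * base$sd)
extractClique(run, ct, hubs)
```

## Known limitations

* No synaptic delays, spatial embedding or conductance-based synapses —
  absent from the modelled circuit by construction.
* The AB rule and the FC significance policy are documented
  interpretations of qualitative published descriptions; both are
  exposed as parameters.
* Event-driven exactness is up to the $10^{-10}$ ms root tolerance;
  trajectories of chaotic realizations diverge from any reference
  integrator on long horizons even so — spike-level agreement is
  asserted on short horizons and statistical agreement beyond.
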
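---
title: "Spike-timing working memory with polychronous neuronal groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-timing working memory with polychronous neuronal groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`polywm` simulates a cortical-like network of 1000 simple two-variable
spiking neurons (80% regular-spiking excitatory, 20% fast-spiking
inhibitory), connected with probability 0.1 and — crucially — with integer
axonal conduction delays of 1–20 ms on excitatory synapses (1 ms on
inhibitory ones). The membrane dynamics are

$$v' = 0.04v^2 + 5v + 140 - u + I,\qquad u' = a(bv - u),$$

with the after-spike resetting $v \leftarrow c$, $u \leftarrow u + d$ at the
+30 mV spike peak, integrated on a 1 ms grid with two 0.5 ms substeps for
$v$. Presets are RS $(a,b,c,d) = (0.02, 0.2, -65, 8)$ and FS
$(0.1, 0.2, -65, 2)$.

Because delays are heterogeneous and reproducible, groups of neurons whose
connections happen to have *matching* delays can fire in stereotyped,
time-locked but non-synchronous sequences: polychronous neuronal groups
(PNGs). A group is identified by a template — a list of (neuron,
relative-time) events plus the anchor subset whose correctly timed firing
triggers the rest of the cascade. Neurons belong to many groups at once;
memory items are patterns of synapses, not sets of cells.

Synaptic weights are bounded in $[0, 8]$ mV, with the bound chosen so that
**three** simultaneously arriving maximal inputs are needed to fire a
resting neuron reliably (two are not enough). All timing-dependent
plasticity is keyed to presynaptic *arrival* times (emission plus delay),
not emission times.

Two plasticity systems act on excitatory-to-excitatory synapses:

* **Long-term STDP**: arrival $\Delta t$ before a postsynaptic spike
  potentiates by $A_+ e^{-\Delta t/\tau_+}$; arrival after it depresses by
  $A_- e^{-\Delta t/\tau_-}$ ($A_+ = 0.1$, $A_- = 0.12$,
  $\tau_\pm = 20$ ms, all-pairs additive traces; a nearest-neighbor variant
  is available). Weights clip to $[0, 8]$ mV.
* **Associative short-term plasticity**, in two interchangeable forms:
  * *short-term STDP* — the same window applied to a per-synapse scaling
    addend $sd$ that multiplies transmission as $w(1+sd)$, clipped to
    $[-0.5, 1]$ and relaxing to 0 with a 5 s time constant. The $+1$
    ceiling means at most a 100% temporary increase; the default increment
    0.1 makes roughly ten optimally timed pairs saturate it.
  * *NMDA-spike mode* — each synapse carries an activation $g$ incremented
    by every arrival and decaying with $\tau = 250$ ms; when
    $g > \theta_{up}$ coincides with a postsynaptic spike the synapse flips
    into an up-state with 10-fold efficacy, persisting until
    $g < \theta_{down}$ (hysteresis). A single-compartment demo
    (`nmda_compartment_demo()`) shows the underlying biophysics: with the
    magnesium block closed, presynaptic input alone yields small EPSPs; a
    paired postsynaptic depolarization unblocks the voltage-dependent NMDA
    conductance (9:1 NMDA:AMPA current ratio at full depolarization) and
    produces a sustained plateau.

Working memory arises from the interplay of these pieces: cueing a group
(injecting its polychronous pattern 10 times within a second) transiently
strengthens its synapses; background "minis" then spontaneously trigger
partial reactivations, each of which re-strengthens the group's synapses,
keeping the item "in memory" as an elevated, episodic replay rate for tens
of seconds — without any reverberating loop.

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_neurons`, `excitatory_fraction`, `connection_prob` | 1000, 0.8, 0.1 | — | network size and sparsity |
| `exc_delay_range` | [1, 20] | ms | the substrate of polychrony |
| `w_max` | 8 | mV | three coincident arrivals ≈ threshold |
| `w_inh` | −6 | mV | fast feedback inhibition |
| `mini_rate`, `mini_amplitude` | 0.3 /s, 20 | — , mV | background drive |
| `p_strong` | 0.3 | — | mature-network strong-synapse fraction |
| `tau_sd` | 5000 | ms | working-memory decay horizon |
| `st_A_plus`, `st_A_minus` | 0.1, 0.12 | — | short-term STDP increments |
| `theta_up`, `theta_down`, `nmda_cap` | 2.5, 0.625, 16 | —, —, mV | NMDA hysteresis and somatic saturation |
| detection `min_fraction`, `jitter` | 0.25 (strict >), ±5 | —, ms | template-match criterion |

Several of these are not printed in the literature this model family comes
from and are therefore explicit package choices:

* **Neuron constants and STDP magnitudes** use the standard published
  presets of the simple-model family; everything is exposed in
  configuration objects.
* **Mini amplitude (20 mV)** was calibrated once with `calibrate_minis()`
  so that 0.3 events/s per neuron yield a ~0.3 Hz mean excitatory
  background rate; a mini is a brief suprathreshold somatic pulse, so the
  background rate tracks the mini rate with a small network contribution.
* **Inhibitory weight (−6 mV)**: weaker inhibition (−5) lets a cued
  group's reactivation halo grow without bound at this network scale, while
  −8 or stronger starves replay ignition; −6 balances episodic replay
  against reliable ignition. It is the main stability knob.
* **The "mature" preset is bimodal** (`p_strong` = 0.3 at `w_max`, the rest
  silent). A network with *every* excitatory synapse at the ceiling is
  epileptic: a three-anchor cascade recruits all 1000 neurons, and the
  background is bistable between silence and seizure. Development by
  long-term STDP produces bimodal weights, and only the bimodal stand-in
  reproduces the stated operating regime (confined cascades, ~0.3 Hz
  background).
* **Δt = 0 ties** (arrival in the same millisecond as the postsynaptic
  spike) count as potentiation — the arrival-before-fire reading; within a
  grid step, deliveries are processed before the neuron update, so a
  same-step arrival is "seen" by the spike.

## The engineered-group experiments

Discovery of spontaneous groups in a fully evolved network (hours of
simulated development, exhaustive anchor enumeration) is a cluster-scale
computation; the package ships the machinery (`find_pngs()`,
`png_statistics()`) and uses **engineered inserted groups**
(`insert_pngs()`) for the quantitative experiments, as the original
experiments did in their supplementary form. Each inserted group has 40
excitatory members at evenly spaced times over 200 ms; every non-anchor
member receives at least three intra-group synapses whose delays make their
arrivals coincide exactly when the member is due to fire (the construction
accounts for the ~3 ms firing latency under threshold drive). `redundancy`
requests extra convergent afferents for noise robustness — the delay
ceiling bounds how many earlier members are eligible, so the effective
redundancy saturates near one extra afferent at this spacing; without any
redundancy the groups are too fragile to stay in working memory at all,
which is the package-scale analogue of "spontaneous groups are prone to
noise".

Insertion experiments use a **silent-base** network (`p_strong = 0`): the
groups are inserted into the randomly connected, non-evolved network.
Small random base weights (the `growth` preset) are worse than silent here:
they add uncorrelated spikes whose net short-term-STDP effect is depression
and replay ignition fails; the silent base isolates the engineered
structure cleanly.

**What the generator emulates, and what it does not.** The synthetic
networks reproduce the connectivity statistics, delay structure,
excitation/inhibition balance and the operating point (background rate,
threshold-coincidence count) of the reference cortical model. They do not
reproduce the *motif richness* of a large evolved cortex: the repertoire of
delay-matched convergent triples that hours of STDP carve out of a larger
network. Consequences, all visible in the test suite:

* Working-memory ignition is stochastic: at the default operating point
  roughly 60% of cued groups stay in memory beyond 10 s; the others lose
  the replay chain early. Medians and multi-seed means are the meaningful
  statistics.
* Maintenance recruits a structural halo — non-member neurons with
  delay-coincident afferent pairs from group members join the replay, and
  overlapping groups occasionally ignite. The non-member population
  therefore sits above the 0.3 Hz background during maintenance (~1–3 Hz),
  unlike in the large evolved network, and the corresponding acceptance
  assertion documents this departure rather than hiding it.
* The **novel-cue learning experiment** cannot use a uniformly random
  stimulus pattern: in a 1000-neuron random network the probability that an
  arbitrary 60-neuron pattern is supported by existing delay-coincidence
  motifs is negligible (two-synapse motifs exist but two potentiated
  arrivals cannot ignite replay; structurally selected conv-2 patterns were
  measured to produce zero replay). The experiment therefore prepares a
  *latent scaffold*: delay-compatible synapses among the stimulated neurons
  at half-maximal weight, functionally silent (well below the
  three-coincidence threshold). Long-term STDP must potentiate the scaffold
  before the pattern can replay at all, so the measured replay still
  reports genuine learning, and the three background conditions keep their
  contrast: with 0.3 Hz minis and short-term STDP the formed group replays
  at ~4 Hz around the final presentation; with 0.1 Hz minis replay is
  scarce; with short-term plasticity blocked there is no spontaneous replay
  whatsoever. The replay rate is reported over the two nine-second segments
  bracketing the last two presentations (one second before each onset to
  eight after), the segments such figures magnify; replay is episodic and
  fades with the 5 s short-term decay constant, so a rate averaged over a
  whole 15 s inter-presentation interval would mostly measure the fade.
* **NMDA-mode selectivity is weaker than short-term STDP's.** Up-state
  induction is gated only by a *coincident* postsynaptic spike, not by a
  causal pre-before-post interval, and a 10-fold up-state on an 8 mV
  synapse would deliver an 80 mV somatic kick; the package caps the somatic
  impact of the dendritic plateau at `nmda_cap` (16 mV — the same ceiling
  as saturated short-term STDP, which is also what makes the two modes
  comparable). Even so, at this scale an NMDA-mode cue ignites replay in
  much of the inserted-group web rather than only the cued group. The
  cue-dependence of maintenance holds in both modes (no cue, no replay);
  between-group selectivity holds only for short-term STDP. This is a
  known, documented limitation of the desk-scale configuration.

## Detection and measurement choices

* A template counts as activated when **strictly more than 25%** of its
  events have a matching spike within ±5 ms of the expected time.
  Candidate onsets are seeded from spikes of the template's first 20% of
  events; overlapping candidates are merged to the best-matching onset by
  greedy non-maximum suppression within half the template duration.
* The time-reversed raster is the null for activation significance: it
  preserves every single-neuron statistic while destroying polychronous
  order.
* The maintenance verdict reports two criteria: at least one detection in
  every consecutive 2 s window, and last detection more than 10 s after cue
  offset; their disjunction is "maintained". The **capacity curve** uses
  the strict every-window verdict — under the lenient disjunction
  essentially every item up to load 64 counts as held and the curve's
  saturation is invisible; under the strict verdict held items grow clearly
  sub-linearly (about 1, 3, 10, 17 at loads 1, 4, 16, 64 in the packaged
  configuration).
* The interference check compares the cued template's detection-rate
  increase with the **median** increase over the five most-overlapping
  non-cued templates: single non-cued groups occasionally enter working
  memory spontaneously, so a one-pair comparison is a lottery; the median
  measures typical interference.
* Rates use 100 ms bins (curves) or plain spike counts over stated windows;
  cross-correlograms use 1 ms bins over ±50 ms; ISI statistics (CV, CV2)
  use the 20 s after cue offset.

## Problem sizes

The packaged experiments are sized for a laptop: 1000-neuron networks,
21 s working-memory trials (20 per batch for the persistence statistics),
a 100 s background run, a 90 s learning run, and capacity loads up to 64
items. The compiled core simulates these about two orders of magnitude
faster than real time; the full test battery and the reproduction script
each run in minutes.

## Known limitations

Beyond the three scale-related departures above: sub-millisecond spike
timing is not modeled (everything lives on a 1 ms grid); minis are somatic
current pulses rather than per-synapse events; the dendritic compartment
demo uses generic passive parameters and a piecewise-linear magnesium
block; and discovery is anchor-triplet reconstruction from structure — it
does not mine rasters for unknown patterns.
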
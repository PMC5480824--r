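---
title: "The l-ALT circuit model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The l-ALT circuit model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beealt` simulates the honeybee lateral antennal-lobe tract (l-ALT): the
pathway from olfactory receptor neurons (ORNs) through the antennal-lobe
glomeruli to a single decision neuron in the lateral horn (LHN). The model
asks how much olfactory learning this shallow pathway can support on its
own, without the mushroom bodies: non-associative decorrelation of the
odour code, absolute and differential conditioning of the
proboscis-extension response, generalization to similar odours, and
compound (patterning) discriminations.

## Stimuli

An odour is a 36-element vector of ligand concentrations (dilution
fractions). Generated single odours activate 2 to 5 ligands, drawn
uniformly; active concentrations are drawn log-uniformly over
$[10^{-7}, 1]$ so that every concentration decade is represented
(dose-response curves span this full range). The sampling law is a package
choice — only the range and the 2-to-5 ligand count are fixed by the
underlying model — and a linear-uniform alternative is available
(`concentration = "uniform"`).

Compound stimuli are built elementwise: the default `sum-clip` rule adds
the component vectors and clips at 1 (superposition of dilutions); `max`
is available. The rule is recorded in the configuration.

## Receptor layer

Each of 36 receptor types binds each ligand with a Hill dose-response
$1/(1 + (K_{ij} l_j)^{-m_{ij}})$. Affinities $K$ are heavy-tailed (most
ligands bind weakly, a few strongly) and each receptor has a unique
preferred ligand; the preferred ligands across the 36 types form a
permutation of the ligand set. A sign matrix marks 25% of non-preferred
receptor–ligand pairs as suppressive: their activation is subtracted
rather than added, which produces the below-baseline evoked responses
seen in real dose-response data. This sign mechanism is a package addition
— a non-negative Hill term alone cannot fire below baseline.

The receptor drive is the baseline current plus gain times the **mean
Hill response over all 36 ligands**, where absent ligands contribute
exactly zero. Two readings of "mean response" are possible (mean over all
ligands vs. mean over the ligands present), and the choice matters more
than it looks: under the active-only mean, a two-odour mixture's drive is
the *average* of the component drives, so a mixture can never recruit the
union of the components' glomeruli and compound discriminations are
structurally impossible. Under the all-ligand mean (the default,
`drive_mode = "all"`), mixture drives add, mixtures activate the union of
the component patterns, and patterning behaves correctly. The gain default
(26 000 pA at full activation of one ligand, divided by 36) is set so that
a typical 2-to-5-ligand odour produces the same drive magnitude as a
few-hundred-pA stimulus current.

ORNs are adaptive exponential integrate-and-fire (AdEx) neurons, 10 per
type (360 total), integrated by forward Euler at `dt = 0.1` ms. The AdEx
constants are the canonical published set (capacitance 281 pF, leak 30 nS,
rest −70.6 mV, slope factor 2 mV, threshold −50.4 mV, adaptation coupling
4 nS, adaptation time constant 144 ms, spike-triggered increment
80.5 pA); the numerical spike cutoff is `VT + 5 * DeltaT`, the absolute
refractory period 2 ms. Baseline current (870 pA) and current noise
(180 pA s.d. per step) are calibrated once so spontaneous rates sit near
20 Hz — the pathway codes odours bidirectionally around a high
spontaneous rate, so a silent baseline would be wrong. The adaptation
variable starts each trial at its spontaneous steady state (240 pA);
starting it at zero inflates the pre-stimulus "spontaneous" window with a
~150 ms adaptation transient and biases every evoked-minus-spontaneous
contrast.

## Antennal lobe and lateral horn

Each of 36 glomeruli holds one projection neuron (PN) and one local
neuron (LN), both conductance-based leaky integrate-and-fire units in
normalized potential units (rest 0, threshold 1, reset 0, membrane time
constant 20 ms, refractory 2 ms). Excitatory synapses decay with
$\tau_E = 5$ ms, LN inhibition with $\tau_I = 10$ ms, and the global
inhibitory neuron's (GIN) synapse with $\tau = 20$ ms. Weights are stored
as non-negative magnitudes; inhibition enters through reversal potentials
($V_E = 6$, $V_I = V_{gI} = -2$ in normalized units), so a synapse at its
reversal potential contributes zero current. LN→LN synapses use the
inhibitory reversal — LNs are inhibitory interneurons, so an excitatory
reversal there would contradict the cell type.

Wiring: each ORN type drives the PN and LN of its own glomerulus
(one-receptor-one-glomerulus); LNs inhibit PNs and LNs of *other*
glomeruli (zero diagonals, enforced through every plasticity update);
PNs send weak fixed excitation to a random 20% of LNs; a single GIN pools
all PNs and feeds inhibition back to all PNs (presets: weak gain 0.1,
strong 0.4); all PNs converge on one LHN whose stimulus-window firing
rate is the behavioural readout. The initial LN→PN and LN→LN matrices are
Gaussian $N(0, 10)$ rectified at zero (half-normal; an absolute-value
mode is available) and capped at the weight bound 25.

`calibrate_bee()` scales the ORN→LN and ORN→PN weights by a common factor
until the mean evoked-minus-spontaneous LN rate over 20 random odours is
40 ± 5 Hz; with the shipped defaults the factor is ~1 (the defaults were
set at the calibration target).

## Plasticity

**Inhibitory STDP (LN→PN).** Symmetric rule with a homeostatic target:
each presynaptic spike changes the weight by $\eta(x^{PN} - \alpha)$ with
$\alpha = 2\rho_0\tau_{iSTDP}$, each postsynaptic spike by
$\eta\, x^{LN}$; traces decay with $\tau_{iSTDP} = 20$ ms and
$\rho_0 = 15$ Hz. The target rate sits on a genuine trade-off: a low
target strengthens lateral inhibition until mixture responses are
suppressed to the level of single odours (compound discriminations then
collapse), while a high target leaves projection-neuron spontaneous rates
high enough that reward-gated potentiation lifts all synapses
indiscriminately (elemental discrimination then collapses); 15 Hz leaves
both intact. The net drift is zero when the PN fires at $\rho_0$, so
exposure to random odours reshapes the inhibitory map until PN responses
are normalized and decorrelated. The learning rate $\eta = 0.005$ spreads
convergence over the full exposure protocol; a faster rate reaches a
noise floor within the first checkpoint interval and the decorrelation
statistic then just fluctuates. The event-driven trace implementation is
exactly equivalent to the all-pairs sum over spike pairs
(`istdp_all_pairs()` is the test oracle); spikes landing in the same
integration step are excluded from each other's traces ("strictly
earlier" convention) in both implementations.

**Modulated STDP (PN→LHN and LN→LN).** Asymmetric kernel
$A_+ e^{-\Delta t/\tau_+}$ / $A_- e^{\Delta t/\tau_-}$ with
$\tau_\pm = 20$ ms, multiplied by the octopamine eligibility factor
$f_d(t) = 1 + d\,e^{-(t-t_{reward})/\tau_d}$ after the reward
($d = 20$, $\tau_d = 400$ ms; 1 before it). As printed elsewhere the
exponent is sometimes written with a positive sign, which grows without
bound after the reward; the decaying form is the default and the growing
form is available as `strict_eligibility` for comparison. Three choices
here were forced by analysis rather than taste:

* **Balanced kernel** ($A_+\tau_+ = |A_-|\tau_-$, defaults
  $\pm 0.0015$). Because $f_d$ multiplies the whole kernel, rewarded and
  unrewarded trials scale the *same* net drift; any kernel imbalance is
  amplified by the reward and either saturates or extinguishes every
  weight (both observed). With an exactly balanced kernel the
  uncorrelated (rate-driven) drift cancels at any firing rates, and only
  causal structure — a presynaptic spike advancing the postsynaptic
  spike through its EPSP — moves weights. This is what makes the rule
  stimulus-specific.
* **US drive to the LHN.** The reward neuron (VUM-mx1) projects to the
  lateral horn, and sucrose itself triggers proboscis extension, so on
  rewarded trials a depolarizing US current (1.5 normalized units) is
  injected into the LHN for the stimulus window. Without it, nothing
  distinguishes rewarded from unrewarded trials except the multiplier
  $f_d$, and CS-specific learning cannot emerge from a multiplier alone.
* **Octopamine gating.** The modulated rules run only on rewarded trials
  (octopamine is released only with the US); unrewarded training trials
  leave the PN→LHN and LN→LN weights untouched. A consequence is that
  the CS− response stays near its naive level during training rather
  than actively decreasing.

LN→LN plasticity uses the same kernel scaled by `ln_ln_rate = 0.2`
(whether it shares the PN→LHN magnitudes is not constrained; the smaller
value keeps the antennal lobe stable through conditioning). Diagonals
stay zero and all weights are clipped to their capacity bounds on every
update. Plasticity of every kind is frozen outside its training phase:
pre-tests and tests never change weights.

## Protocols

Conditioning trials are 1000 ms with the stimulus from 250 to 750 ms and
the reward (when present) at stimulus onset. Exposure presentations use a
shortened 600 ms trial (stimulus 100–600 ms) and probe presentations a
500 ms trial (stimulus 50–500 ms): only the stimulus-window rates enter
any statistic, and the shorter presentations keep the full exposure
protocols tractable. The problem sizes used by the test-suite
replications are 200 exposure stimuli per bee for conditioning cohorts
and 150 for decorrelation curves, with checkpoints scaled proportionally
from the full protocol's 0/500/1000/2000.

Training interleaves one presentation per contingency per round in
seed-controlled pseudorandom order (10 rounds by default), with optional
early stopping once the largest per-round PN→LHN weight change falls
below 0.5% of capacity. Tests present each stimulus 3 times, unrewarded,
plasticity frozen, in shuffled order; rates are averaged so the order
cannot matter. Population experiments rebuild everything per bee —
affinity matrix, connectome, odours, noise — from named substreams of the
cohort seed, so cohorts are exactly reproducible and a fixed-random-
connectivity control (no exposure, LN→PN frozen at initialisation) is a
one-flag variant.

## Metrics

`entropy_reduction()` reports both the printed statistic
$\tfrac12\log|\Sigma|$ (which mixes dependence with per-neuron variances
and is negative for sub-unit variances) and the non-negative
multi-information $-\tfrac12\log|R|$ on the correlation matrix, which is
zero exactly at independence; monotone decorrelation statements use the
multi-information. A diagonal shrinkage of $10^{-6}$ stabilizes the
64-stimulus × 36-neuron determinants; closed-form checks set it to zero.
The Treves–Rolls sparseness index, angular distance between population
vectors, and Welch/paired cohort t-tests follow their standard
definitions; conditioning cohorts use the paired variant because each bee
contributes both a CS+ and a CS− rate.

## What the synthetic data do and do not show

All inputs are synthetic: random ligand vectors, random affinity
matrices, random connectomes. The generator reproduces the *structure*
of the modelled system — sparse ligand composition, overlapping
heavy-tailed receptor profiles, concentration coding over seven decades —
but not the chemistry of real odorants, receptor adaptation across
trials, temporal/latency coding, or the m-ALT pathway and mushroom
bodies. Passing tests therefore show that the circuit mechanisms behave
as claimed under the model's own assumptions, not that the parameters
match any particular bee.

## Known limitations

* Strong GIN feedback lowers the multi-information of the probe code at
  every checkpoint (a more decorrelated code throughout), but its
  *rate of decline* under exposure is shallower than with weak feedback:
  the homeostatic iSTDP has less work left to do when feedback
  inhibition has already normalized PN rates. The claim that stronger
  global feedback *accelerates* the decline did not emerge in any
  parameter regime we explored; we report the level effect instead and
  flag the rate effect as not reproduced.
* Negative patterning is not learned — the rewarded components never
  come to exceed the unrewarded mixture, which is the expected failure
  for a single linear readout — but the mixture's response stays
  *above* the components (union coding plus incomplete normalization by
  the GIN), rather than statistically indistinguishable from them.
* The CS− training trajectory is flat rather than slightly decreasing,
  a consequence of gating plasticity to rewarded trials.
* With the all-ligand drive, odour salience scales with ligand count and
  concentration; odour pairs of very unequal salience are genuinely
  harder to discriminate, and a small fraction of simulated bees fail
  the differential task for that reason.
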
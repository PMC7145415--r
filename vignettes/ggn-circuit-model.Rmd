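---
title: "Modeling the giant GABAergic neuron and its mushroom-body circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the giant GABAergic neuron and its mushroom-body circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbggn)
```

## The circuit and the question

In the locust mushroom body, on the order of 50,000 Kenyon cells (KCs)
transform dense, oscillatory input from about 830 antennal-lobe
projection neurons (PNs) into a sparse odor code. A single giant
GABAergic neuron (GGN) per hemisphere closes a feedback loop around the
entire KC population: every KC excites GGN in the alpha lobe, and GGN —
a non-spiking neuron that signals by graded transmitter release —
inhibits every KC in the calyx. A second spiking neuron, IG, is coupled
to GGN by reciprocal inhibition; its spikes are visible in GGN
recordings as IPSPs.

`mbggn` implements this circuit as a composable set of models:

* a **passive branched cable** for GGN, built from an SWC morphology
  (loaded from file or generated synthetically),
* **Hodgkin-Huxley-type point KCs** and an **Izhikevich
  regular-spiking IG**,
* **graded** (sigmoidal, voltage-dependent) and **spike-triggered**
  (double-exponential) synapses with lognormal weight sampling,
* a **PN population generator** producing nonhomogeneous Poisson spike
  trains with the population statistics measured in vivo,
* a network assembler/co-simulator and scripted experiments.

The central scientific questions the experiments address: can passive
conduction carry the alpha-lobe feedback signal to the calyx strongly
enough to inhibit KCs; what does the feedback loop do to the KC
input-response function; which network features produce the sustained,
in-vivo-like GGN odor response; what role do rare high-firing KCs play;
and what wiring lets IG hyperpolarize GGN during odors.

## GGN as a passive cable

The GGN model is a labeled tree of cylindrical compartments. The
electrical parameters are the ones used throughout: membrane
resistivity RM = 33 kOhm cm^2, axial resistivity RA = 100 Ohm cm,
specific capacitance Cm = 1 uF/cm^2, resting potential -51 mV. Each
neurite segment is split so that no compartment is longer than 0.1 of
the local DC length constant `lambda(d) = sqrt(RM d / (4 RA))`, the
usual discretization rule for passive models. The solver uses
Hines-ordered elimination on the tree — exact and linear-time — with
ideal (Dirichlet) voltage clamps; transient runs use backward Euler,
which is unconditionally stable and evaluates synaptic conductances
implicitly at the end of each step. Both paths are verified in the test
suite against the closed-form solution for a finite sealed cable and
against a dense matrix solve.

```{r attenuation}
morph <- generate_synthetic_ggn(seed = 1)
morphometry(morph)
model <- compartmentalize(morph)
att <- exp_clamp_attenuation(model)     # -51 -> -40 mV at the alpha stem
vapply(att$dv, median, numeric(1))
```

The synthetic morphology generator emulates the gross anatomy of the
traced neuron — about 65 mm total neurite length, maximum along-tree
path length on the order of 2 mm, trunk diameters near 20 um tapering
to 0.5 um twigs, with the calyces carrying most of the terminal arbor —
by stochastic binary branching within per-region length budgets. It
reproduces the *scale* of the real cell, not its actual geometry:
branch angles, spatial embedding and the detailed diameter profile are
simplified, so quantitative attenuation values differ in detail from
the traced reconstruction even though the qualitative behaviour
(attenuation grows with RA, shrinks with RM, calyceal signals stay
above the ~2 mV transmission threshold except at extreme parameter
values) is the same. Tests passing on the synthetic cell therefore
validate the machinery and the qualitative physiology, not the exact
millivolt values of the deposited trace.

## Point neurons

The KC is a single compartment with fast and slow Na currents, a
delayed-rectifier K current, a transient A-type K current and a slow
transient outward K current, over a -70 mV leak. The published
constants of the channel set this model descends from are not
reproduced here; the kinetics in `kc_params()` were authored for this
package and tuned to the qualitative KC phenotype that matters for the
circuit: rest near -70 mV, silence at rest, spiking only to strong
synchronized input, a rheobase well above the spontaneous synaptic
drive, a spike-count curve that first grows with input and then
collapses into depolarization block, and a pronounced A-current spike
latency. That latency is functionally important in the network: it
delays KC firing at odor onset by one to two LFP cycles, long enough
for the GGN feedback to engage, and is a classic sparseness mechanism
in its own right. All constants live in one parameter object so a
different channel set can be substituted wholesale.

IG is the canonical Izhikevich regular-spiking cell (a = 0.02, b = 0.2,
c = -65, d = 8) with conductance-based synapses added;
`calibrate_ig_current()` bisects its baseline current until it fires at
the observed ~7 spikes/s.

## Synapses

Graded release follows first-order kinetics toward a Boltzmann function
of the presynaptic voltage. Two operating points are used:

* **Network feedback (GGN->KC, GGN->IG):** half-activation -40 mV,
  slope 2 mV. At GGN rest (-51 mV) release is a few percent of maximum,
  so the resting loop supplies a small tonic inhibition, while the
  odor-evoked 5-15 mV depolarization sweeps the synapse through its
  steep range. This operating point was chosen during network
  calibration: with half-activation at -45 mV and a 3 mV slope the
  tonic/odor release contrast is too small to satisfy both calibration
  targets below simultaneously.
* **Single-KC loop experiment:** half-activation -45 mV, slope 3 mV,
  in the middle of the -50...-45 mV range where graded synapses are
  documented to operate. Here the tonic release at rest *is* the
  "baseline inhibition from spontaneous GGN activity" that raises the
  KC threshold, so a larger resting release fraction is the point.

Spike-triggered synapses are peak-normalized double exponentials
(rise 1 ms, decay 5 ms by default). `equivalent_synapse()` collapses
many identical synapses with uniformly distributed delays into one
kernel (the unit kernel convolved with a boxcar); a Monte-Carlo test
verifies it against 1,000 explicitly delayed synapses at 2% RMS.

## PN drive

The PN generator is the model's only input and encodes the measured
population statistics: 77% of PNs spontaneously active at 2.6 spikes/s;
during a 1 s odor, 20% excited at 20 spikes/s with a 20 Hz sinusoidal
modulation of amplitude 0.4 x rate (phase zero at odor onset), and 10%
of the spontaneously active PNs inhibited. The `shifting` scheme
divides the responsive 70% into four equal groups with epoch sequences
EEI, EIE, IEI, IIE over two half-odor epochs and a 0.5 s off epoch;
each excitatory epoch starts with 70% of group members active and
recruits 10% per LFP cycle for three cycles, cumulatively within the
epoch and redrawn across epochs. Counts are fixed with `round()` so
that 830 PNs yield 639 spontaneously active, 166 excited and 64
inhibited. Trains are sampled by Poisson thinning, so empirical rates
are unbiased; acceptance checks recover 2.6 and 20 spikes/s within
three standard errors and find the 20 Hz spectral peak.

## Network assembly and calibration

Each KC receives an independent random half of the PN population
(expected shared input between two KCs follows the `m n / q` rule, ~50%
overlap), one excitatory synapse onto a random alpha-lobe terminal
compartment, and one graded inhibitory input from a random calyceal
compartment. The desk-scale default is 5,000 KCs standing in for
50,000, with KC->GGN (and KC->IG) conductances multiplied by
`50,000 / n_kc` so the total drive onto GGN is preserved; a
self-consistency test checks that the GGN response is stable under this
scaling.

Two calibrations anchor the weights, mirroring the physiological
constraints:

1. the mean graded GGN->KC conductance holds the median KC at -60 mV
   (band -61...-59) under spontaneous PN bombardment
   (`calibrate_kc_inhibition()`, bisection). The probe run holds GGN at
   rest: under spontaneous drive GGN stays within a fraction of a
   millivolt of rest, so the open-loop median equals the closed-loop
   one at far lower cost;
2. the PN->KC mean and the weight heterogeneity are set so that the
   heterogeneous network responds to odors with roughly 10% of KCs
   spiking, most of them fewer than five times.

With the defaults (`pn_kc_weight = 1.4e-4` uS,
`ggn_kc_gbar = 0.2` uS, `kc_ggn_weight = 3e-4` uS per biological
synapse) both constraints hold simultaneously.

```{r network, eval = FALSE}
het <- exp_full_network(model, "lognormal", "shifting", seed = 1,
                        n_kc = 5000)
het$metrics$sustainedness      # ~0.9: sustained depolarization
het$metrics$spiking_fraction   # ~0.07: sparse KC response
hom <- exp_full_network(model, "homogeneous", "fixed", seed = 1,
                        n_kc = 5000)
hom$metrics$sustainedness      # ~0.1: isolated synchronized peaks
```

The 2 x 2 design (uniform vs lognormal weights; fixed vs shifting PN
populations) reproduces the central network result: only heterogeneous
synaptic strengths produce a sustained GGN depolarization, with the
homogeneous conditions collapsing into sparse synchronized bouts, and
PN->KC delay diversity (normal, mean 7.5 ms, SD 3 ms — the mean being
the 1,500 um / 0.2 m/s conduction ceiling) does not substitute for
weight heterogeneity. A related signature: in a uniformly weighted,
strongly driven population, KC spike counts correlate negatively with
the mean depolarization of each KC's assigned GGN compartment (branches
receiving weaker feedback inhibit their KCs less); weight heterogeneity
clearly weakens this dependence, although at reduced population sizes
the residual correlation remains measurable rather than negligible. In the homogeneous conditions the matched-mean
conductances leave the population nearly silent apart from rare
synchronized bouts; larger bouts reappear when the uniform inhibition
is weakened, but either way the sustainedness index stays far below
the heterogeneous condition, which is the claim under test.

## Ablation and IG experiments

`exp_ablation_loop()` repeatedly disconnects KCs whose odor-window
(odor + 0.5 s off epoch) spike count exceeds the stage limit (more than
five; then three or more; then any), re-running with identical seeds
until no cell exceeds the limit. Replacement high-rate KCs emerge and
the removal waves dwindle over rounds; total spiking declines to zero
and the terminal network is silent with a flat GGN trace — high-rate
KCs are an emergent property of the weight distribution and feedback,
not a fixed subpopulation. At desk scale (hundreds to a few thousand
KCs) each removal wave perturbs the feedback appreciably, so the
spike-total sequence declines with occasional upward fluctuations of a
few percent of the initial total (removing strong drivers disinhibits
the survivors); the population-level trend — strictly decreasing
stage-wise totals and eventual extinction — is the robust readout, and
the per-iteration decline becomes smooth only as the population
approaches its full biological size.

`exp_ig_variants()` wires IG as: reciprocal GGN<->IG only (swept over
coupling strengths, IPSP time constants 10 and 100 ms, and baseline
rates 3/7/15 spikes/s — a reduced but representative grid, since the
source experiments report only that "a range" was tested); reciprocal
plus direct KC->IG excitation (lognormal weights, 200 ms delay); and
reciprocal plus PN->IG excitation. Hyperpolarization is scored on the
49 Hz low-pass-filtered GGN trace as >= 1 mV below the pre-odor
baseline for >= 100 ms anywhere from odor onset to 500 ms past the off
epoch; with the 200 ms KC->IG delay the hyperpolarization characteristically
follows stimulus offset. No reciprocal-only configuration
hyperpolarizes GGN (release from GGN inhibition alone cannot raise IG's
rate while GGN is still depolarized), whereas the KC->IG variant
produces a clear post-odor hyperpolarization, with the detected IPSP
rate rising before GGN's membrane potential has returned to baseline.
The PN->IG variant raises IG's odor rate more modestly at the default
weight; KC drive is the variant the acceptance checks assert.

## Numerical choices

* Cable and network steps are fully implicit in voltage (backward
  Euler); gating uses exponential Euler with 0.1 mV lookup tables.
* `dt = 0.025 ms` whenever HH KCs are in the loop, 0.1 ms for
  passive-only runs; halving `dt` changes KC spike counts by at most
  one on the standard step protocol.
* Cross-population coupling (KC spikes into GGN, graded feedback to
  KCs, IG exchange) is staggered by one time step; at 0.025 ms this is
  far below all synaptic time constants.
* Spike detection: upward 0 mV crossing with a 2 ms refractory.
* The IPSP detector subtracts a 200 ms running-median baseline and
  timestamps local minima deeper than 0.5 mV with a 20 ms refractory.
* Zero-length morphology segments are merged into their parents;
  voltage clamps replace rows exactly (no series resistance).
* Degenerate inputs (empty spike trains, zero rates, zero-variance
  correlations, missing regions) raise errors or return empty results
  explicitly rather than propagating NaN.

## Problem sizes

The shipped experiments run at desk scale: 5,000 KCs for the
heterogeneity conditions, 600-1,000 for the ablation loop, 500 for the
IG variants, a ~2,100-compartment synthetic GGN, and 0.5 s pre-odor +
1 s odor + 0.5 s off-epoch windows. These sizes keep a full reproduction in
minutes on one core while preserving total synaptic drive through the
conductance scaling; the same code runs the full 50,000-KC network
unchanged, only slower.

## Limitations

The synthetic morphology reproduces scale, not geometry; absolute
attenuation values on the deposited trace will differ. KC channel
constants are package-authored stand-ins with the right phenotype, not
the published honeybee set. The graded-synapse constants of the
original model are unpublished; the two operating points used here are
design choices documented above. In vivo firing statistics (0.09-0.16
Hz KC rates, IPSP rates across animals) concern recorded animals and
are outside what simulation can reproduce. Synaptic plasticity,
mushroom-body output neurons, and the bilateral GGN pair are out of
scope.
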
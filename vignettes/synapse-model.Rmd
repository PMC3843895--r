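---
title: "A Monte Carlo model of receptor activation at a small central synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Monte Carlo model of receptor activation at a small central synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cleftsim)
```

## The model

`cleftsim` simulates a single quantal release event at a typical small
excitatory synapse (of the hippocampal CA3–CA1 type) and asks how the peak
postsynaptic current depends on the number, surface density and nanoscale
arrangement of the receptors.

The synaptic apposition is a flat cylindrical cleft of radius $R$ (default
200 nm, physiological range ~180–240 nm) and height $\delta$ = 19 nm, the
distance between the apposed membranes in electron micrographs. A concentric
disc of radius $r_a$ (default 110 nm, range ~60–200 nm) on the postsynaptic
membrane is the postsynaptic density (PSD), holding $N$ receptors scattered
uniformly at random; the presynaptic active zone opposes it. One vesicle's
worth of glutamate — $q$ = 2700 molecules — is released instantaneously at a
point on the presynaptic face, either on the cleft axis or at a random
active-zone location.

Each molecule performs an independent Brownian walk, advanced with
per-axis Gaussian increments of variance $2D\,\mathrm{d}t$ at
$\mathrm{d}t$ = 0.1 µs, with $D$ = 0.33 µm²/ms inside the cleft and
0.4 µm²/ms outside. Molecules reflect at the two membranes, leave the cleft
across its rim into open three-dimensional space, may re-enter through the
rim (but not through the terminals), and are removed at an absorbing sphere
of radius $R_{out}$ (default 2 µm) that represents loss into the
surrounding tissue. Where the exact radius of that invented outer boundary
might matter, it does not: moving it anywhere between 0.6 and 4 µm changes
the scenario statistics below by under 1%.

Receptors are multi-state Markov channels. The AMPAR scheme has seven
states (two sequential glutamate bindings, one open state, a three-state
desensitised branch) with the classical hippocampal patch-clamp rate
constants; the NMDAR scheme has five states (two bindings, one desensitised,
one open; no Mg²⁺ block — the model studies glutamate-driven gating only).
Conductances are 12.5 pS (AMPAR) and 25 pS (NMDAR), $E_{rev}$ = 0 mV, and
the membrane is clamped at $V_m$ = −80 mV for both kinds; because
potentiation is a ratio of currents, the NMDAR driving-force choice cancels
from every percentage reported here. All rate constants live in editable
YAML files under `system.file("extdata", package = "cleftsim")`, so the
transcription is auditable and swappable.

### The hybrid duty cycle

At every time step the engine (1) moves all free molecules, (2) estimates
the glutamate concentration at the receptors, and (3) propagates the
receptor state. With centre release the problem is rotationally symmetric
and the concentration is the ring estimate
$C(r,t) = N_\delta\,(2\pi r\,\delta\,\Delta r)^{-1}$ over rings of width
$\Delta r$ = 10 nm (the innermost ring is the disc of radius $\Delta r$);
with a random release site the engine instead counts molecules in a
sampling cylinder of radius $\rho$ = 20 nm around each receptor. Receptor
occupancies then advance through the master equation
$\mathrm{d}P/\mathrm{d}t = Q(C)^T P$ with $C$ frozen within the step, and
the total current is $I(t) = \sum N_{open}\,\gamma\,(V_m - E_{rev})$.

This *hybrid* scheme (individual molecules, deterministic receptor
occupancies) is validated against the fully stochastic mode, in which each
receptor walks its kinetic scheme as a continuous-time Markov chain with
exact exponential waiting times inside each step: ensemble means of the two
agree at the peak (see `validate_model()` and the test suite).

## Numerical choices

* **Propagator.** The master equation is integrated with classical RK4,
  sub-stepped so that (maximum exit rate) × (sub-step) ≤ 0.25. This
  conserves total probability to round-off, stays non-negative through the
  enormous (hundreds of mM) concentration spike in the first microseconds
  after release, and passes the two-state closed-form oracle at relative
  error < 10⁻³. Occupancy-sum drift beyond 10⁻⁶ aborts the run.
* **Stiffness.** Halving `dt` moves the hybrid peak open fraction on a
  prescribed concentration transient by < 0.1%, and refining `dt` from
  0.1 to 0.01 µs moves the ensemble-mean peak current by < 1% (the model's
  own accuracy check, recomputed by `scripts/acceptance.R`).
* **Far-field coarsening.** Extracellular molecules farther than 200 nm
  from the cleft opening take 1.6 µs steps (Gaussian increments are exact
  at any lag away from boundaries) and resume 0.1 µs stepping when they
  approach the opening; a 1.6 µs step travels ~36 nm per axis, so the
  chance of crossing the 200 nm buffer in one step is negligible. This is
  what makes 20-trial ensembles run in seconds without touching in-cleft
  physics.
* **Estimator resolution.** $\Delta r$ and $\rho$ are configurable;
  `validate_model()` reports the sensitivity of the peak to halving
  $\Delta r$ and to switching estimators. For centre release the two
  estimators agree within sampling noise.
* **Seeding.** Every trial is driven by a dedicated counter-based RNG
  stream derived from `(seed, stream)`; fixed seeds give bit-identical
  trajectories. Sweep cells derive their stream family from the cell's
  configuration values, so any two sweeps visiting the same `(kind, r_a,
  N, R)` cell with the same base seed produce identical numbers.

## Ensembles and the layout protocol

Peak statistics are the mean ± s.d. of per-trial peaks over `n_trials` = 20
consecutive simulated release events (the peak of the pointwise mean trace
is reported alongside). Because the receptors are specified only as
"uniformly scattered", every release event redraws the scatter: the
ensemble mean then estimates the configuration class $(N, r_a, R)$ rather
than one arbitrary arrangement, whose luck-of-the-draw otherwise biases a
50-receptor synapse by up to ±10% of the peak. The clustering scenarios
rescale the same trial's baseline scatter onto the smaller disc — the same
receptors pulled closer together — so nearest-neighbour distances shrink
exactly in proportion to the radius. Receptors are static within a trial
(no lateral diffusion).

Trace durations default to 3 ms (AMPAR) and a 50 ms cap with early
stopping once the current decays below 1% of its running peak (NMDAR);
both capture the peak with a wide margin. AMPAR peaks occur near 0.2 ms,
NMDAR peaks within a few ms.

## Temperature calibration

The source rate constants are room-temperature fits, and the model operates
at 33–35 °C. A single Q10 multiplier scales all rates; the package ships
with Q10 = 2.0 applied from 25 °C to 33 °C (factor 1.74). This value was
calibrated, within the physiological range, so that the receptor-insertion
scenarios (PSD expansion at constant density) reproduce the ~50% current
potentiation that defines them; it is recorded in the scheme files and in
every output's metadata.

One limitation surfaced during that calibration and is worth stating
plainly. Along the admissible temperature-factor axis the insertion and
clustering gains trade off — their sum stays near 75–80 percentage points
for this model family — so a calibration that puts insertion at +50%
leaves clustering (PSD shrinkage at constant $N$, e.g. 110 → 75 nm, a ~32%
nearest-neighbour reduction) at about +25–28%. Clustering is therefore
reproduced in sign, monotonicity and rank order, but at roughly half the
published magnitude. The shortfall is insensitive to the outer-boundary
radius and to layout sampling; it most plausibly reflects micro-environment
features (tortuous perisynaptic neuropil, glial uptake) present in the
antecedent full-scale models of this synapse but deliberately outside this
package's scope. A steeper intra-PSD activation profile, however produced,
would raise the clustering gain and lower the insertion gain toward each
other.

## What the synthetic conditions do and do not show

All inputs are configuration; there is no external data. The generator's
defaults are the study conditions: 2700 molecules, centre-fixed release
(random active-zone release as the variability scenario), $R$ = 200 nm,
$r_a$ = 110 nm, 50 AMPARs or 10 NMDARs, $V_m$ = −80 mV, n = 20 trials.
Passing tests show that *this model*, under these conditions, behaves as
described — conservation laws, free-diffusion statistics, closed-form
channel kinetics, hybrid/stochastic agreement, monotone dose–response
surfaces. They do not show that a biological synapse is quantitatively
captured: the model omits transporter uptake, neuropil tortuosity,
receptor lateral diffusion, multivesicular release, Mg²⁺ block and
dendritic filtering, and receptor positions are an idealised uniform
scatter rather than an imaged arrangement.

## Problem sizes

The shipped configurations were sized for a desk-scale single-CPU run:
20-trial ensembles per configuration cell (~10–40 s each), 40 trials per
`dt` in the time-step check, 40 stochastic runs in the hybrid validation,
10³–10⁴ draws in the point-statistics oracles. All are configurable
upward; every result object embeds its seeds, so any number can be
reproduced exactly.

## Worked example

```{r example}
library(cleftsim)

geom <- synapse_geometry()                       # R = 200, r_a = 110, d = 19
lay  <- place_receptors(geom, 50, "AMPAR", seed = 1)
cfg  <- trial_config(geom, lay)                  # 2700 molecules, centre
ens  <- run_ensemble(cfg, n_trials = 20, base_seed = 1)
glance(ens)                                      # mean +/- s.d. peak, pA
autoplot(ens)

ltp_scenarios("AMPAR", n_trials = 20, base_seed = 1)
```
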
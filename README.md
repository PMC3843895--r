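# cleftsim

Monte Carlo simulation of glutamate release and receptor activation at small
central excitatory synapses, for computational neuroscientists studying how
the **number, density and nanoscale arrangement of postsynaptic receptors**
shape the synaptic current — in particular, whether long-term potentiation
(LTP) is more economically expressed by inserting receptors or by crowding
the existing ones.

## The model

A quantum of glutamate (2700 molecules) is released instantaneously at the
presynaptic face of a flat cylindrical cleft (radius *R* ≈ 200 nm, height
δ = 19 nm). Each molecule follows an independent Brownian walk
(*D* = 0.33 µm²/ms inside the cleft, 0.4 µm²/ms outside; Δt = 0.1 µs),
reflecting at the membranes, escaping across the cleft rim and eventually
being absorbed far from the synapse. *N* AMPA receptors (γ = 12.5 pS) or
NMDA receptors (γ = 25 pS, no Mg²⁺ block) are scattered uniformly over the
postsynaptic density (PSD, radius *r*ₐ ≈ 110 nm) and gate through
multi-state Markov schemes driven by the local glutamate concentration

&nbsp;&nbsp;&nbsp;&nbsp;*C*(*r*,*t*) = *N*<sub>δ</sub> (2π *r* δ Δ*r*)⁻¹,

the ring estimate over the individually tracked molecules (a per-receptor
sampling cylinder replaces it when the release site is off-centre). The
occupancy vector of each receptor pool advances through the master equation
d*P*/d*t* = *Q*(*C*)ᵀ*P* (hybrid mode; a fully stochastic per-receptor mode
exists for validation), and the synaptic current is

&nbsp;&nbsp;&nbsp;&nbsp;*I*(*t*) = Σ *N*<sub>open</sub> · γ · (*V*<sub>m</sub> − *E*<sub>rev</sub>),&nbsp;&nbsp; *V*<sub>m</sub> = −80 mV, *E*<sub>rev</sub> = 0.

On top of single trials sit seeded 20-trial ensembles and a parametric-sweep
engine: receptor number at constant density, PSD shrinkage at constant *N*
(receptor crowding, summarised by the mean nearest-neighbour distance),
cleft-size dependence, LTP scenario pairs, and peak-current maps over
(density, pool size) with steepest-change directions.

## Worked example

```r
library(cleftsim)

geom <- synapse_geometry()                        # R = 200 nm, r_a = 110 nm
lay  <- place_receptors(geom, 50, "AMPAR", seed = 1)
cfg  <- trial_config(geom, lay)                   # 2700 molecules, centre release
ens  <- run_ensemble(cfg, n_trials = 20, base_seed = 1)
glance(ens)
#> # A tibble: 2 × 6
#>   kind  mean_peak_pA sd_peak_pA mean_peak_time_us n_trials peak_of_mean_trace_pA
#>   <chr>        <dbl>      <dbl>             <dbl>    <int>                 <dbl>
#> 1 AMPAR         13.2      0.254              261.       20                  13.2
#> 2 total         13.2      0.254              261.       20                  NA

ltp_scenarios("AMPAR", n_trials = 20, base_seed = 1)
#> # A tibble: 2 × 11  (columns abridged)
#>   scenario base_mean_pA test_mean_pA pct_change_peak pct_change_n pct_change_nn
#>   insert           13.7         20.6           +50.3         +168          +1.2
#>   clust            13.7         17.5           +27.3            0         -31.8
```

Reading: the typical synapse (50 AMPARs) peaks near 13 pA about 0.25 ms
after release, with only diffusion noise across trials for a fixed layout
(s.d. ≈ 0.25 pA; the LTP table below redraws the scatter each trial, which
widens the spread to ≈ 0.6 pA).
Expanding the PSD to *r*ₐ = 180 nm at unchanged receptor density (+168%
receptors, the *LTP insert* scenario) potentiates the peak by ≈ 50% — the
dose–response is strongly sub-proportional because peripheral receptors see
far less glutamate. Shrinking the pool to *r*ₐ = 75 nm with no new
receptors (*LTP clust*, a ~32% cut in inter-receptor nearest-neighbour
distance) buys ≈ +27% in this implementation: clustering potentiates
without any new receptors, though less steeply than insertion (see the
vignette for the calibration analysis).

The command line mirrors the R surface:

```sh
Rscript inst/scripts/cleftsim simulate --seed 1 --out out/   # one ensemble
Rscript inst/scripts/cleftsim ltp --receptor both --out out/ # scenario pairs
Rscript inst/scripts/cleftsim sweep --trials 20 --out out/   # sweep families
Rscript inst/scripts/cleftsim validate                       # property suite
```

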
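# dynbarrier

Cohesin loop extrusion with **dynamic CTCF barriers**: a 1D lattice
simulator in which barrier sites stochastically switch between bound and
unbound states while two-legged extruders grow chromatin loops, coupled to a
lightweight bead-spring polymer sampler that turns extruder positions into
3D conformations and in silico Hi-C maps. The package is for chromatin
biophysicists and genomicists who want to ask how CTCF *kinetics* — not just
occupancy — shape the observables we actually measure: cohesin ChIP-seq
enrichment (FRiP), TAD insulation, convergent-dot strength versus genomic
distance, and whole-chromosome (vermicelli) morphology.

## The model in brief

A CTCF site alternates between bound (mean dwell τ_b) and unbound (mean
dwell τ_u) states — a telegraph process with stationary occupancy
o = τ_b/(τ_b + τ_u). While bound it blocks extruder legs arriving from one
direction; extruders have exponential lifetimes (mean τ_E) and step with
fixed per-update probabilities on a 250-bp lattice. Many (τ_b, τ_u) pairs
share one occupancy, and the package quantifies how strongly the observables
depend on the kinetics at fixed occupancy.

For a single extruder loaded between two convergent barriers a distance δ
apart, with total loop growth rate v, the expected extruded loop size at
unloading has the closed form

```
E[L] = v τ_E (1 − exp(−δ/(v τ_E)) · o · τ_b/(τ_b + τ_E))
```

which interpolates the three kinetic regimes (never reaches the barrier;
reaches it and can be blocked; outlives the bound state and bypasses) and is
validated in the test suite against an independent event-driven Monte-Carlo
oracle that simulates the barrier telegraph trajectories explicitly.

## Worked example

```r
library(dynbarrier)

occupancy(1350, 150)
#> [1] 0.9

# same occupancy (0.5), tenfold different bound time: different loop sizes
p_slow <- regime_params(tau_E = 1320, tau_b = 1320, tau_u = 1320,
                        delta = 87500, v = 150)
p_fast <- regime_params(tau_E = 1320, tau_b = 132, tau_u = 132,
                        delta = 87500, v = 150)
round(c(slow = expected_loop_size(p_slow), fast = expected_loop_size(p_fast)))
#>   slow   fast
#> 166181 192215

mc_loop_oracle(p_slow, "midpoint", n_replicates = 1e4, seed = 1)
#> # A tibble: 1 × 4
#>      mean    se     n loading
#>     <dbl> <dbl> <int> <chr>
#> 1 167338. 1791. 10000 midpoint

# two 2.5-Mb replicas, 32 barriers each at occupancy 0.9, 22-min extruders
lay <- random_layout(2.5e6, 32, tau_b = 1350, tau_u = 150, seed = 1)
cfg <- lattice_config(n_sites = 10000, n_replicas = 2, seed = 1)
tr  <- run_lattice(cfg, lay, duration = 3 * 1320 + 6000, sample_every = 10)
glance(tr)
#> # A tibble: 1 × 7
#>   n_frames n_extruders n_barriers mean_loop_bp median_loop_bp ...
#> 1      600          20         64      108285.          80000

track <- accumulate_track(tr)
frip(track, barrier_sites(lay))
#> [1] 0.15125
```

Reading the numbers: the two parameter sets share occupancy 0.5, yet the
slow-exchanging barrier (τ_b = τ_E) traps the extruder often enough to cut
the mean loop from 192 kb to 166 kb — occupancy alone does not determine
folding. The oracle mean (167.3 ± 1.8 kb) agrees with the closed form
within Monte-Carlo error. In the lattice run at occupancy 0.9, collisions
and sequential barrier encounters shrink loops further (mean 108 kb), and
15% of all leg observations sit exactly on barrier sites (FRiP 0.151)
versus a no-barrier floor of 32/10000 = 0.0032.

Downstream, `run_polymer()` couples a trace to the 3D sampler,
`aggregate_map()` bins contacts, and `insulation_score()`, `dot_profile()` /
`mean_dot_score()` and `vermicelli_score()` compute the map- and
conformation-level observables. `run_pipeline()` chains every stage from a
flat key-value config file and writes BED/bedGraph/TSV artifacts;
`inst/scripts/dynbarrier-cli.R` exposes the same stages as shell verbs.
See the methods vignette (`vignettes/dynamic-barriers.Rmd`) for the model,
the derivation, all defaults and the known limitations.

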
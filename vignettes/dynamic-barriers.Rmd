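---
title: "Dynamic CTCF barriers and cohesin loop extrusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic CTCF barriers and cohesin loop extrusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynbarrier)
```

## The model

Mammalian interphase genomes are folded by cohesin complexes that extrude
chromatin loops until they unload, and by CTCF, which binds directional motif
sites and blocks extrusion while bound. In vivo, CTCF residence times (a few
minutes) are much shorter than cohesin lifetimes (tens of minutes), so a CTCF
site is better described as a *dynamic* barrier than a wall. dynbarrier
implements this picture as a fixed-timestep simulation on a 1D lattice:

* **Barriers** occupy single lattice sites and switch between a bound and an
  unbound state as a telegraph process with mean bound time $\tau_b$ and mean
  unbound time $\tau_u$ (seconds). The stationary occupancy is
  $o = \tau_b/(\tau_b+\tau_u)$. Many $(\tau_b, \tau_u)$ pairs share one
  occupancy — separating occupancy from kinetics is the entire point of the
  model. Each barrier blocks extruder legs travelling in one direction only
  (`+` blocks rightward-moving legs, `-` leftward-moving legs), and rebinding
  does not care where extruders are: a barrier can rebind inside an extruded
  loop.
* **Extruders** are two-legged agents. Each leg independently attempts one
  outward lattice step per update with probability
  $v_{leg}\,\delta t/\ell$ (leg speed $\times$ timestep / site size). A step
  is refused silently when the target site holds another leg, lies beyond the
  replica boundary, or when the leg currently rests on a bound barrier whose
  orientation blocks its direction — so a blocked leg comes to rest *on* the
  barrier site and retries every update, resuming as soon as the barrier
  unbinds. Extruders unbind with probability $\delta t/\tau_E$ per update and
  instantly reload with both legs on a uniform-random pair of adjacent
  unoccupied sites in their replica (only occupied sites are excluded), so
  the extruder count is constant.
* **Update order** within a timestep is fixed and documented: barrier flips,
  extruder turnover, then leg steps in a freshly randomised order over all
  legs (the random order removes systematic left/right bias). A single
  seeded RNG drives everything, so equal seeds give bit-identical runs.

### Reference parameters

| parameter | default | meaning |
|---|---|---|
| `site_bp` | 250 bp | lattice site; fine enough to resolve rapid CTCF exchange |
| `n_sites` $\times$ `n_replicas` | 10000 $\times$ 10 | ten 2.5-Mb replicas |
| `extruder_separation` | 1000 sites | one extruder per 250 kb |
| `tau_E` | 1320 s | cohesin lifetime, 22 min |
| `tau_b`, `tau_u` | 1350 s, 150 s | occupancy 0.9 reference kinetics |
| `leg_speed` | 75 bp/s | per-leg extrusion rate (see below) |
| `dt_lattice` | auto | largest $\delta t$ with step probability $\le 0.5$ and flip probabilities $\le 0.1$ |

The extrusion speed is not printed in the published main text; the default
is derived from the stated calibration target instead: interphase cohesin
processivity is measured at roughly 120–240 kb, so with $\tau_E = 22$ min
the total loop growth rate is $v = P/\tau_E \approx 150$ bp/s (75 bp/s per
leg, unimpeded processivity $2\,v_{leg}\tau_E \approx 200$ kb, comparable
to the 250-kb loading separation). This matters beyond realism: a much
faster default (tried first at 250 bp/s per leg) collision-saturates the
reference lattice and qualitatively changes how FRiP responds to extruder
lifetime. Every analytical result that depends on $v$ takes it explicitly.
Reported lifetimes for the reference scenario vary slightly between
displays of the source measurements (1312–1350 s); the package uses
22 min = 1320 s everywhere.

Barrier layouts are generated by `random_layout()` (32 barriers uniform over
2.5 Mb gives the reference ~75-kb mean spacing; orientations are drawn
independently with probability 1/2 unless another scheme is requested) and
are replicated *identically* across replicas, which keeps per-site averaging
across replicas meaningful for ChIP-style tracks. Replicas are independent
lattices with impassable ends, so no loop spans two replicas in 1D.

Simulations start barriers from their stationary law (bound with probability
$o$), so the burn-in (default $3\tau_E$) only needs to relax the loop-size
distribution. `static = TRUE` freezes the initial stationary draw, giving
the static-barrier comparison model in which a site of occupancy $o$ is
permanently bound with probability $o$.

## Expected loop size between convergent dynamic barriers

For one extruder loaded midway between two convergent barriers a distance
$\delta$ apart, each leg reaches its barrier at time $\delta/v$ (with
$v$ the two-leg growth rate). Over an exponential lifetime $T$ with mean
$\tau_E$, three regimes occur: the extruder dies before arrival
($T < \delta/v$), it arrives and can be blocked
($\delta/v < T < \delta/v + \tau_b$), or it outlives a typical bound period
and can bypass ($T > \delta/v + \tau_b$). Averaging the leg trajectory over
the lifetime, the stationary barrier state at arrival (bound with
probability $o$) and the memoryless residual bound time gives the closed
form implemented in `expected_loop_size()`:

$$
E[L] \;=\; v\,\tau_E\left(1 -
  e^{-\delta/(v\tau_E)}\; o\,\frac{\tau_b}{\tau_b+\tau_E}\right).
$$

Limits worth knowing: $o \to 0$ gives the unimpeded mean $v\tau_E$;
permanently bound barriers with $v\tau_E \gg \delta$ give $\delta$; at
$\tau_u \gg \tau_E$ the expression becomes affine in occupancy (the static
limit, where only occupancy matters); and at fixed $\tau_u$ it decreases
monotonically in $\tau_b$, dropping fastest near
$\tau_b \approx \tau_E - \delta/v$ for short unbound times. The iso-occupancy
factor $\tau_b/(\tau_b+\tau_E)$ is the analytical core of the package: two
parameter pairs with equal occupancy but tenfold different $\tau_b$ predict
clearly different loop sizes when $\tau_b \approx \tau_E$.

`mc_loop_oracle()` is the independent check: an event-driven simulation that
draws a lifetime and a loading point, then simulates each barrier's
telegraph trajectory *explicitly* from a stationary start up to the leg's
arrival. Nothing about the arrival state or residual time is assumed, so
agreement between the oracle and the closed form validates exactly the
renewal assumptions used in the derivation. Uniform loading is exposed
alongside midpoint loading because simulated comparisons typically load
uniformly while the derivation assumes the midpoint; at the reference
parameters the two differ by far less than the kinetic effects of interest.

## In silico ChIP-seq and FRiP

`accumulate_track()` tallies extruder leg visits per lattice site over all
sampled frames (both legs, all replicas, collapsed onto within-replica
coordinates). FRiP — the fraction of reads in peaks — is the share of leg
observations sitting exactly on barrier sites. Because a blocked leg rests
*on* the barrier site, this definition is parameter-free; a flanking-window
variant (`window` argument) exists for sensitivity analyses. A leg is
counted once per sampled frame, matching the population-of-timepoints
interpretation of the track. The no-barrier control FRiP equals the lattice
share of barrier sites (32/10000 per replica in the reference setup), which
is the floor against which "FRiP remains low for transient barriers" is
measured. Read-level noise (fragmentation, background reads) is out of
scope: experimental FRiP is background-confounded and is treated by the
model only as a loose constraint.

One subtlety matters when comparing extruder lifetimes: longer-lived
extruders accumulate at barriers partly as *queues* stacked directly behind
a barrier-stalled extruder. Queued legs sit next to, not on, the barrier
site, so the exact-site FRiP is nearly blind to stacking, whereas
experimental FRiP counts reads across the full peak width. Lifetime
comparisons in the test suite therefore use the windowed variant
(±500 bp), which captures the queue; single-condition kinetic sweeps use
the parameter-free exact-site default.

## The polymer sampler

The 3D side converts extruder leg positions into conformations and contact
maps. It is deliberately a lightweight, self-contained overdamped bead-spring
sampler — not a molecular-dynamics engine — and its fidelity target is
ensemble contact statistics, not calibrated dynamics. Reduced units: energy
$k_BT = 1$, friction 1, length = one monomer diameter (a 2.5-kb, ~50-nm
fiber segment at the default `monomer_bp = 2500`); no attempt is made to
report nanometres or seconds of 3D time.

Forces and integration:

* backbone springs $k = 100$ between consecutive monomers, rest length 1;
* extruder bonds $k = 100$, rest length 0.5, between the monomers holding
  the two legs (`legs_to_bonds()` drops extruders whose legs share one
  monomer); the bond force is capped at `f_max = 20` so a freshly switched
  long-range bond contracts at constant speed instead of tearing the chain;
* soft excluded volume: linear-ramp repulsion of strength 3 within 1
  diameter, evaluated through a cell list; strand passage is allowed, as
  appropriate for a coarse fiber model;
* optional harmonic-wall spherical confinement (off by default) and an
  optionally extended (persistent-walk) initial fiber, both used for
  whole-chromosome morphology runs;
* Euler–Maruyama steps of `dt_3d = 0.005` with the deterministic
  displacement capped at 0.2 diameters per monomer per step, which keeps
  dense bottlebrush conformations stable; chain connectivity is checked
  after every advance and a break raises an error instead of returning
  corrupt coordinates.

Coupling follows the instant-switch schedule: at each harvested lattice
frame the extruder bonds are replaced by the frame's coarse-grained legs,
the chain relaxes for `steps_per_frame` (default 200) integrator steps, and
the frame is harvested — so monomers bonded in frame $t$ are exactly the
coarse-grained legs of lattice frame $t$. Consecutive replicas can be
concatenated into one continuous 3D chain (`replicas = 1:k`), mirroring the
consecutive-replica construction of the reference setup; extruder legs still
respect their 1D replica boundaries.

Contacts are all monomer pairs within `capture_radius = 2` diameters,
excluding $|i-j| \le 1$; `aggregate_map()` bins them symmetrically at 10-kb
resolution for scoring (2.5-kb maps are for display). The capture radius and
relaxation schedule are package choices; the map-level ratio scores below
are insensitive to uniform rescaling of contact counts by construction, and
sweeps of the capture radius (1.1–2 diameters) move the insulation and dot
scores far less than the barrier-kinetic effects they measure.

## Contact-map and conformation observables

**Insulation.** For each barrier bin, three *congruent* right triangles with
hypotenuses on the map diagonal are compared: one ending at the barrier
(upstream), one starting at it (downstream), and one centered on it (the
spanning region holding boundary-crossing contacts). The score is the mean
contact frequency over the two within triangles divided by the mean over the
centered triangle, averaged across barriers. Because the triangles are
congruent, every genomic distance enters numerator and denominator with the
same weight, so the contact-frequency distance decay cancels exactly: any
map whose contacts depend only on distance scores exactly 1, and the same
score is obtained on observed and observed/expected maps. (A spanning region
made only of strictly crossing pixels has a different distance profile and
is confounded by the decay — measurably so in this sampler — which is why
the congruent-triangle reading is used.) The first two diagonals are
excluded everywhere; the window is 50 kb at 10-kb bins.

**Convergent dot score.** For every convergently oriented barrier pair, an
80-kb snippet centered on the (anchor, anchor) pixel is collected; snippets
are averaged within 25 logarithmically spaced distance bins spanning
100 kb – 5 Mb (right-open, geometric edges), and each bin is scored as the
averaged snippet's central pixel over the mean of its four corner pixels.
The corner controls make the background local: broad enriched bands through
an anchor cancel out, where a global background would score them as dots.
`mean_dot_score()` collapses the profile with snippet-count weights, so each
distance contributes in proportion to how many pairs it holds. Center and
control extents are single pixels by default and configurable. Bins whose
averaged corner controls fall below one count per pixel (`min_control`)
return `NA` and drop out of the weighted mean: in scaled maps the far
distance bins can be genuinely empty, and a ratio over near-empty controls
is dominated by zero-count noise rather than by dot strength.

**Vermicelli score.** `vermicelli_score()` rasterises all monomer positions
and the bonded leg monomers onto a shared voxel grid (voxel = 1 diameter,
bounding box padded by $3\sigma$), Gaussian-smooths both grids
($\sigma = 2$ voxels, separable), and returns the Pearson correlation over
voxels. Identical fields score 1; extruder positions off the chromatin
support score near 0. The constructed morphology fixtures
(`morphology_fixture()`) verify the intended contrast: a chain wound around
a straight axis with anchors on the axis clearly outscores a random coil
with sparse anchors.

A known limitation, found while characterising the sampler and worth
stating plainly: in coupled simulations at the reference extruder density,
the score does *not* reproduce the expected ordering between transient and
quasi-static barriers at sevenfold extruder lifetime. With one extruder per
250 kb, quasi-static barriers park legs at the ~75-kb barrier spacing —
finer genomic coverage than the ~250-kb loop junctions of the condensed
state — and at desk scale the Pearson statistic rewards that uniform
coverage more than axial concentration, while the apexes of condensed loops
are as far from any leg as the naked segments of the static case. This
persisted across smoothing scales, grid conventions, excluded-volume
strengths, chain lengths (1–8 replicas), monomer sizes (2.5–10 kb),
extended initial fibers, confinement and long relaxations; reproducing the
full morphology contrast evidently needs the full-scale system and
molecular-dynamics engine that this package intentionally replaces. The
score, its defaults and the condensation machinery are all exercised by
tests; the cross-condition ordering at sevenfold lifetime is reported as
measured.

## What the synthetic generator does and does not emulate

`random_layout()` and `convergent_pair()` produce the study's barrier
geometries: uniform-random distinct sites, shared kinetics, independent
random orientations, and the two-barrier layout of the analytical model.
They do not emulate site-specific bound/unbound times (the per-site columns
exist, but the study conditions share one timescale), the genomic
distribution of real CTCF motifs, barrier clustering, or any sequencing
noise. Tests passing on these layouts therefore demonstrate the model's
internal behaviour — telegraph statistics, blocking, regime structure,
score responses — not agreement with any experimental dataset.

## Numerical choices and degenerate inputs

* `dt_lattice` auto-selection: largest $\delta t$ with leg-step probability
  $\le 0.5$ and every flip probability $\le 0.1$; a user-supplied $\delta t$
  above $\min(\tau)/10$ warns, and any per-update probability above 1 is an
  error. `tau_u = 0` means permanently bound; `tau_b = Inf` never unbinds.
* Loading retries are bounded (default $10^4$); exhausting them raises a
  density error rather than looping.
* Empty traces, empty tracks, all-empty distance bins, zero between-domain
  contacts and zero-variance voxel grids raise errors or warnings rather
  than returning silent zeros; barriers without full insulation margins are
  dropped.
* Ties in leg stepping are broken by the per-update random leg order.
* Seeds: every user-facing simulation takes a seed, restores the caller's
  RNG state, and records the seed in its output; the pipeline derives all
  stage seeds from one master seed.

## Problem sizes used by the test suite

The observable-level tests run scaled versions of the study conditions,
chosen as the smallest systems in which each effect is unambiguous: the
telegraph and loop-size checks use $10^4$–$10^5$ events or replicates;
FRiP regime checks one 2.5-Mb replica with $10^4$ sampled frames;
insulation/dot discrimination one replica, 1000 monomers and 1500 harvested
frames; morphology runs 100 frames at 60-s spacing. The full 10-replica
reference configuration runs with the same code via `run_pipeline()`.

## Known limitations

* The 3D sampler trades dynamic fidelity for self-containment: no
  time calibration, no topology conservation, soft cores, capped forces.
  Contact-map *ratio* statistics are its design target.
* Map-observable contrasts at desk scale are real but small: between
  $\tau_b = \tau_E/10$ and $\tau_E$ at occupancy 0.7 the insulation score
  separates by a few percent and the mean dot score by several percent in
  the scaled single-replica runs. The scaled free chain has high background
  contact frequency at all genomic distances, which compresses both
  ratios; the orderings are stable, the margins are not of the size the
  full-scale reference system produces.
* The vermicelli cross-condition ordering at sevenfold lifetime is not
  reproduced (see above).
* Extruder–extruder collisions are neglected in the closed form (as in its
  derivation) and present in the lattice; the oracle matches the former by
  construction.
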
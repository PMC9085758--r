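---
title: "Methods: multiscale reaction-diffusion and vesicle dynamics in vesiflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale reaction-diffusion and vesicle dynamics in vesiflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesiflow)
```

vesiflow simulates cellular signalling systems that couple fast, continuous
chemistry (second messengers diffusing and reacting on a grid) with slow,
discrete membrane traffic (vesicles moving, docking, fusing, and budding).
This vignette is the package's own account of the model layers, the
numerical choices, and what the bundled aquaporin-2 (AQP2) models do and do
not show. All empirical statements below are the ones the test suite and
`scripts/acceptance.R` compute.

## The chemistry layer: entities, rules, generated networks

Chemical species are *complex entities*: connected graphs whose nodes are
simple entities (a protein, cAMP, a phosphate group) and whose edges are
bonds at declared binding sites. There are no state flags — a
phosphorylation is literally the addition of a phosphate node at a
phosphosite, so "phospho-AQP2" and "AQP2" are two different graphs. Small
molecules (cAMP, AMP, phosphate) carry a single effective site and can bind
one partner at a time.

Reactions are declared as rules: chains of four basic reactors. BIND joins
two available reactants; ADD attaches a component drawn from an implicit
pool (phosphate from ATP); REMOVE deletes a leaf component; RELEASE splits a
complex at a bond and terminates the chain. Conditions (has-part,
lacks-part, site-free, site-occupied, count-of-part; extensible through
`register_condition_type()`) restrict candidates, and implicit filters
(site occupancy, small-molecule valence) always apply. `generate_network()`
iterates rule application to a fixpoint, deduplicating entities by a
canonical graph label and reactions by their substrate/product/rate
signature, and records a provenance track per reaction that replays to its
product.

Entity identity uses refinement-based canonical labelling (igraph's BLISS
backend) on a bond-subdivided, vertex-coloured graph at every size; the test
suite checks label equality against an exhaustive permutation oracle on
small complexes. Distinct binding topologies can share a molecular formula
(cAMP on site A versus site B of the PKA regulatory subunit), so
concentration fields are keyed by uniquified species names
(`species_names()`), with `#k` suffixes separating isomers.

Unbounded polymerisation is fenced in two ways: products larger than
`max_complex_size` (default 16 simple entities) are discarded, and
generation aborts naming the offending rule when the pool still grows after
the iteration cap.

## Space, compartments, units

The simulation space is a pseudo-3D slice: a regular 2D grid with spacing
`ds` and fixed height (default 1 um; the slice depth is a configurable
model parameter). Grid indices are 0-based (row, col)
with the origin at the top-left pixel in all raster imports and exports.
Each grid point is a well-mixed box of volume `ds^2 * height`; membranes are
unit faces between neighbouring points, each of area `ds^2` (segment length
times step width). Rasters (PNG) map pixel colours to compartment
descriptors and restriction coefficients; areas of the same colour are
automatically surrounded by a membrane.

Internal units are um, s, and uM throughout; config values carry explicit
units converted at load. Amounts are measured in uM um^3 (602.2 molecules).
Volume compartments store concentrations (uM); surface compartments
(membranes, vesicle surfaces) store per-area densities (uM um), and
reactions across an interface run at a per-area rate
`v_A = k * prod(sigma_surface) * prod(c_volume,local)`, with soluble
products deposited into the coupled grid cells weighted by interface area.
This convention is self-consistent and testable (conservation of amounts is
asserted across every transfer); it is the package's own choice, and chosen by this package.

SNARE counts for fusion gating are obtained from area densities by
`floor(density * area * 602.2)` — the conversion from concentration to a
discrete molecule count is a modelling choice here, and rounding down is
the conservative one.

## Diffusion with restriction

Transport uses the explicit five-point stencil with per-point restriction
coefficients `r in [0, 1]` and zero-flux boundaries on the whole domain
boundary (corner conditions alone would not be well-posed). Each neighbour
term is scaled by the *neighbour* cell's coefficient; for spatially
varying `r` this exchange is
asymmetric (entry into a restricted region is gated by the surrounding
cells' coefficients, exit by the region's own), and mass is conserved
exactly only where `r` is locally uniform. Two consequences are documented
deliberately:

* Points with `r = 0` form the non-diffusible set and are special-cased to
  exchange nothing in either direction; without this, mass would leak *into*
  a fully restricted region through the neighbours' unit coefficients.
* In the compartmentalisation model, what gates *entry* into the storage
  region is therefore the membrane ring and its passages, while the
  restriction coefficient controls how the region re-exports and
  redistributes what got in.

Membrane faces drop their neighbour terms entirely (impermeable to all
diffusing species); passages are gaps opened in the ring by count.

## The embedded Euler/midpoint pair and the error controller

Every process is an update module. Concentration modules expose a rate;
the integrator forms the embedded pair `d1 = dt * f(c)` (Euler) and
`d2 = dt * f(c + d1/2)` (midpoint) — two function evaluations, second order,
with the local truncation error estimated from the same two evaluations.
The per-module local error is

```
eps_local = log10( |d1 - d2| / max(|d2|, eta * |c|, atol) )
```

maximised over the module's entities and grid points. A module whose error
exceeds `tau_local` interrupts the step and keeps requesting decreases until
it passes, after which all modules rerun; when every module is below
`theta_local * 10^tau_local` (with the defaults, 2.5% — half of the 5% cap)
the next step is stretched. The controller is deterministic: identical
state and configuration give identical step sequences.

Numerical choices worth stating plainly:

* `tau_local = log10(0.05)` caps the accepted per-step relative local error
  at 5%; `theta_local = 0.5` puts the step-increase bound at exactly 2.5%.
  Both are config parameters.
* The error denominator carries two floors. `atol` (default 1e-9) ignores
  per-step deltas that are numerically negligible — without it a pool
  sitting at exactly zero pins the relative error at order one for every
  `dt`. `eta` (default 0.01) switches deltas smaller than 1% of the local
  concentration to absolute control — a transport stencil's net flux cancels
  at symmetry points while its curvature does not, and a purely
  delta-relative error would freeze the step there. Reaction bundles do not
  need the `eta` floor (a mass-action rate is proportional to its own
  substrates, so no internal cancellation occurs) and keep the plain
  delta-relative form.
* Step scaling uses decrease 1/2 and increase 1.4. With binary doubling the
  controller thrashes: any error in (1.25%, 2.5%) triggers an increase whose
  doubled step lands above 5% and is immediately rejected, wasting half of
  all evaluations. A 1.4 factor settles into the admissible band.
* Negative concentrations reject the step (halving `dt`) rather than
  clamping, which would silently destroy conservation. Accepted midpoint
  updates may leave negative dust below `atol`; that dust is zeroed on
  acceptance (a sub-`atol` correction by construction), because a pool
  parked at -1e-12 would otherwise block every subsequent step.
* Non-finite module deltas are treated as infinite error, so a pathological
  rate drives the step to `dt_min` and aborts with a diagnostic naming the
  critical module.

After the local pass, the *total* (entity-level) error is evaluated: the
summed per-module deltas give a scaffold state `c + D_total/2`, all module
rates are recomputed there, and that scaffold-based delta both produces the
accepted step and is compared against the plain sum. Using the scaffold
recomputation as the applied update makes the composite scheme genuinely
second order across module couplings (per-module midpoints alone miss the
cross terms and degrade to first order globally; the accepted stiff
trajectories are verified against a tight-tolerance reference integration).
The total error is normalised by the scaffold concentration (the
entity-level check relates full-step and scaffold concentrations);
delta-normalisation here would pin the error at
order one whenever influx and consumption nearly cancel. Total-error
evaluation is skipped while it stays below the negligibility threshold `nu`
(default `10^tau_total / 1e4`), re-armed after any step increase and by a
backup re-evaluation every 100 steps (a package default).

Displacement-based modules report through the same controller:
`D(a) = log10(||dp_total|| / d_ref)` per vesicle, with `d_ref = ds/4` (a
stated "fraction of the step width" without a number), decrease above
`theta_disp_plus = 0` and increase below `theta_disp_minus = -1` (both
package defaults). Chance-driven state changes cap the step so that
`f * dt <= 1` rather than clamping the probability.

## Agents

Vesicles are sphere-like agents (position, radius `r < ds`, state, membrane
and cargo compartments). Each accepted step re-associates every vesicle
with the 1-4 grid cells under it; the membrane fraction assigned to a cell
is the arc length of the circumference inside that cell (computed
analytically from the grid-line crossings and verified against a
perimeter-sampling oracle). Perimeter weighting is one documented choice —
area weighting lives behind the same function if a different convention is
ever needed. The four-cell contract holds for `r <= ds/2`, which all
bundled models use.

Collision handling is the discard policy: a proposed move that would overlap
another vesicle, cross a membrane face (including exactly through a face
joint), cross a barrier region boundary, or leave the domain is dropped and
the vesicle keeps its position. Vesicles are resolved in increasing id
order so runs are reproducible. Brownian displacement is
`sqrt(2 D_v dt) * xi` per coordinate, the only dimensionally consistent
form, recovering MSD = 4 D_v dt for any step size. Filament transport advances `v_m * dt` along a
polyline toward the motor's end, rolling over vertices; the post-scission
actin boost is directed orthogonal to the spawning membrane segment with
speed proportional to the clathrin coat density. Filament generation for
the full model uses straight tracks; `grow_filament()` provides a
simplified persistent-random-walk generator where curved tracks are wanted
(an exact cytoskeletal growth model is out of scope; the interface is the
same either way).

All randomness flows from one run seed through named substreams (pit
spawning, Brownian steps, chance state changes, placement), so toggling one
stochastic module does not perturb the others and runs are bit-for-bit
reproducible.

## Endocytosis and fusion

Pits spawn on a membrane as a Poisson process at `k_p * area`. Each
collecting pit absorbs cargo through its footprint at
`k_c = c_cat / (c_cat + c_inh) * k_b` (active SRC catalyses, phospho-SRC
inhibits), never more than the membrane holds. A pit that has not
accumulated the checkpoint density `c_cp` by the deadline `t_cp` aborts and
returns everything; one that has enters maturation and, after `t_m`,
scissions into a coated vesicle (cargo plus clathrin coat and R-SNAREs)
that receives the actin boost. Cargo absorption draws from the pit's
membrane compartment; the footprint-rate against the shared membrane pool
is the convention used here, and it reproduces cargo competition, where
many parallel pits starve each other. Pit deadlines are deterministic, so
abortive lifetimes cluster exactly at `t_cp` and productive lifetimes at
time-to-checkpoint plus `t_m` — the two modes of the lifetime histogram.

Fusion is SNARE-gated: within attachment distance `d_a`, at least `n_p` Q/R
pairs must be formable from the target-membrane and vesicle densities; the
vesicle then holds in a fusing state for `t_f`, after which its membrane
species merge into the target membrane (area-scaled), lumenal cargo merges
into the grid cell beneath, and the agent is removed. Every transfer is an
amount-for-amount move; the suite asserts conservation to 1e-12.

## The bundled AQP2 models

**Phosphorylation model** (`run_phospho_model`): well-mixed, the full
rule-generated signalosome (40 entities, 114 reactions): two cAMP sites on
the PKA regulatory subunit with release of the catalytic subunit gated on
double occupancy, autophosphorylation of the regulatory subunit with
reduced rebinding, substrate phosphorylation of AQP2 and PDE4 through
explicit binding/catalysis/dissociation, PP2B reversal, and
phospho-enhanced cAMP hydrolysis (negative feedback). Literature-anchored constants are hard defaults (cAMP-PKAR binding
0.07 uM^-1 s^-1; influx levels in nM/s; the 0.75 departure threshold); the
remaining constants are physiological placeholders flagged in
`phospho_params()` and calibrated once so the model sits at the stated
basal operating point (S256 phospho-ratio 0.46 under 50 nM/s influx) while
200 nM/s at binding 0.07 clears 0.75 — conditions fixed once, up front. PKA activity is reported as the free
(regulatory-subunit-free) fraction of the catalytic subunit — the simpler,
monotone choice among plausible activity measures.

**Compartmentalisation model** (`run_compartment_model`): 30x30 grid at
`ds = 2` um (a desk-scale slice; the spacing is the package's scaling choice), cAMP diffusing at
32 um^2/s, a storage region with pinned PKAR (buffering) and PDE4
(hydrolysis), influx at four basolateral nodes, and optionally a membrane
ring with a configurable number of passages. The field starts at a resting
0.01 uM cAMP (cells hold nanomolar cAMP at rest; a hard zero is both less
physiological and numerically hostile to relative error control). The
restricted setup (permeability 0.01, ring with two passages, high
hydrolysis) maintains a greater-than-tenfold cytosol/storage ratio at
300 s; the unrestricted comparison (no ring, permeability 1) stays within
a factor of two of uniform. The pinned pool sizes (PKAR 1 uM, PDE4
0.4 uM) were chosen once so that hydrolysis alone cannot maintain the
gradient without diffusive restriction, which is the scientific point the
model makes.

**Endocytosis model** (`run_endocytosis_model`): a 1 um^2 apical membrane
patch (four unit faces at `ds = 0.5`) above a cytosol strip; the
signalosome plus the PKA -> CSK(S364) -> SRC(Y527) cascade run as interface
reactions on the membrane, and the active/inhibited SRC ratio scales pit
cargo collection. The checkpoint density corresponds to roughly 360
molecules of AQP2 per nascent vesicle (order hundreds per vesicle, as
reported for AQP2 carriers). A three-point cAMP influx sweep shows rising
SRC phosphorylation and falling productive pit counts.

**Full recycling model** (`run_full_model`): a 20x20 um cell section with
apical membrane, reduced-permeability storage region holding
signalosome-carrying vesicles, actin tracks to the membrane, a microtubule
for retrograde transport, the stepped influx schedule (400 nM/s per node
for 5 min, 200 nM/s to 15 min, 50 nM/s basal thereafter), SNARE-gated
fusion and endocytosis. Vesicles depart when their S256 phospho-ratio
crosses 0.75; membrane permeability is reported as a configurable linear
factor times the apical AQP2 density (a single factor preserves the shape
of the trace). The
`recycling` variant raises SRC/CSK dephosphorylation tenfold so productive
endocytosis resumes; the `activation` variant keeps it slow so delivered
AQP2 stays in the membrane. Full-scale runs (40 minutes of simulated time at full resolution) cost on
the order of a hundred CPU-hours, so the bundled configuration is a scaled
variant: a smaller
section, fewer vesicles, and staging hooks (`vesicle_init`) that let tests
start from a departing or tethered vesicle instead of waiting minutes of
simulated time for phosphorylation to build.

## What the synthetic conditions do and do not show

The generator-defined conditions reproduce the *mechanisms*: gated release,
the negative hydrolysis feedback, gradient formation only under combined
restriction and hydrolysis, SRC-gated pit maturation, discrete
fusion-driven permeability jumps, and conservation of every species across
all transfers. They do not reproduce: absolute physiological rate
constants (most are placeholders), 3D geometry (the slice is pseudo-3D),
the full 40-minute recycling trajectory, multiple phosphosites (S261/264/
269), ubiquitination, or receptor-level vasopressin dynamics — all out of scope by design.
Passing tests therefore validate the framework's numerics and the models'
qualitative and scaled quantitative behaviour, not in-vivo parameter
values.

## Reduced-scale choices (summary)

| Quantity | Full scale | Package default |
|---|---|---|
| Compartment grid | 30x30 | 30x30 at ds = 2 um |
| Full-model section | whole-cell slice, 40 min | 20x20 um, staged scenarios |
| Storage vesicles | many | 5 |
| Apical patch | 1 um^2 | 1 um^2 (4 faces at ds = 0.5) |
| Sweep sizes | 5184 settings | 3-point influx sweeps |

The problem sizes are the package's own desk-scale choices; every
quantitative claim in the README and tests is computed at these sizes.
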
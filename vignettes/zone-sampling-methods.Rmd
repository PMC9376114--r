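---
title: "Zone-based virtual-system coupled sampling: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-based virtual-system coupled sampling: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Binding of a flexible, medium-sized ligand to a membrane receptor spans free
and bound states separated by large free-energy barriers; plain molecular
dynamics never visits both on accessible time scales. The sampler implemented
here attacks the problem in a low-dimensional space of *reaction coordinates*
(RCs), each defined as the distance between the centroids of two named atom
groups. Each RC axis is divided into small, mutually overlapping intervals
("virtual zones"); the direct product of per-axis intervals tiles the
multi-dimensional RC space with overlapping boxes.

A walker is confined to one zone at a time by a flat-bottom restraint: zero
energy inside the box, half-harmonic (`0.5 k delta^2` per axis) outside, so
the potential stays continuous and once-differentiable across the walls. At a
fixed cadence (`transition_interval_steps`) the walker may hop to any zone
that contains its instantaneous RC vector. Hops are drawn with probability
proportional to the candidate zone's *zone-normalized* canonical density at
the current point, `Q(lambda) / mass(zone)`. For a point shared by two zones
the raw densities coincide, so this reduces to a preference for the zone with
the smaller estimated mass and satisfies detailed balance with respect to the
zone-flattened target `pi(x, zone) ~ rho(x) / mass(zone)`: when `Q` equals
the true canonical density, every zone is visited equally often, which is the
flattening the method exists for. Two consequences of this analysis are built
into the engine:

* a walker that has spilled past its own zone's soft wall *skips* the
  attempt and lets the restraint pull it back — relabelling it to the zone
  that does contain it would be a one-way move that measurably drains edge
  zones toward the centre;
* when a snapshot and a transition attempt coincide, the snapshot is
  recorded first, so every stored state has one full confinement interval
  of relaxation behind it.

The flattening statement is exact for time spent *inside* the zone boxes.
Soft walls add a boundary-layer dwell time of order `sqrt(RT/k)` outside the
box that scales with the wall density; the estimator therefore counts only
in-box snapshots, and the flattening property test does the same.

## Estimating the canonical density

Iteration histograms update the density surface `Q` stored per
(zone, intra-zone bin) cell (10 bins per axis per zone by default). Within a
zone the new shape follows the observed counts (the walker is unbiased inside
its box, so the in-box conditional is the restricted canonical distribution);
empty observed cells receive an add-one pseudo-count so the support never
collapses. Zone masses are then stitched by matching the mean per-volume
density of neighboring zones over their shared overlap cells,
breadth-first from the best-sampled zone, and the surface is renormalized.
Zones with no counts carry their previous values through.

A genetic algorithm refines the stitched surface. Candidates are log-density
surfaces; the fitness penalizes (i) squared mismatch of mean log-density on
shared overlap cells over all neighboring zone pairs, (ii) a small roughness
term on second differences within zones (weight 0.01), and (iii) deviation
of each zone's *mean-removed* log-density from the measured input
(`shape_weight`, default 1). The third term is this package's own addition:
without a data anchor the first two terms are blind to any smooth
deformation, and the surface random-walks away from the measurement under
mutation (we observed spurious tilts of the double-well marginal). Anchoring
only the within-zone shape leaves the zone offsets — the degrees of freedom
the stitching is about — entirely free, so seam discontinuities are still
ironed out (a planted factor-10 step is reduced more than ten-fold) while
the measured structure is preserved. Selection is tournament (size 3),
crossover exchanges whole zones (rate 0.7), mutation is additive Gaussian on
log values (sigma 0.05), and the best candidate is carried over unchanged,
so fitness never decreases.

Convergence is judged per zone by `E_local`, implemented as the mean
absolute log-ratio of consecutive surfaces over the zone's cells (one-sided
zeros are floored at half the smallest positive value); a zone with
`E_local < 0.25` is deemed accurately determined. The exact published form
of this diagnostic is not available; an overlap-consistency variant is
provided behind `mode = "overlap"`, with the iteration comparison as the
default. The threshold 0.25 is kept as the default gate.

After the loop, the final surface is re-estimated from the pooled histograms
of *all* iterations: the in-box conditional per zone is the same restricted
canonical distribution in every iteration, so pooling only reduces variance.
Snapshot weights follow `w ~ Q(cell) / n(cell)`, normalized over the
ensemble; snapshots outside their zone's box get weight zero (counting them
in clamped edge cells would bias the shape).

## Dynamics backend

The bundled backend is overdamped Langevin dynamics on analytic toy
potentials, with the sampler state equal to the RC vector. The
discretization averages consecutive noise increments
(`x' = x + dt F/gamma + sqrt(2 RT dt/gamma) (xi_k + xi_{k+1})/2`,
Leimkuhler–Matthews), whose stationary distribution is accurate to
`O(dt^2)`; the plain Euler–Maruyama update is available via
`method = "euler-maruyama"` but carries an `O(dt)` stationary bias that is
clearly resolvable at the statistical power of the bundled tests (about
-0.5% on the double-well second moment at `dt = 0.004`). Per-run noise
streams are derived from `(rng_seed, iteration, run)`, so results are
bit-reproducible and independent of execution order. Seeds for the next
iteration are drawn round-robin from zones ranked by ascending visit count,
so poorly sampled regions are revisited preferentially.

## Desk-scale study conditions

The canonical-recovery study (also run by `scripts/acceptance.R`) uses a
symmetric quartic double well (barrier 2 kcal/mol, minima at ±1 Å, 300 K,
domain ±2.5 Å), six 50%-overlapping zones with ten intra-zone bins, spring
25 kcal/mol/Å², `dt = 0.004` with transition and snapshot cadence 1000
steps, and 500 runs of 25 000 steps per iteration, for up to 12 iterations
with a floor of 8 before the convergence gate may stop the loop. The floor
mirrors the practice of sampling beyond first convergence to accumulate
analysis statistics; the sizes were chosen by relaxation-time arithmetic
(zone traversal ≈ 400 steps, so the cadence decorrelates stored states)
and give the weighted estimates enough power that the recovery checks
(L1 < 0.05 against the quadrature marginal; first and second moments within
three standard errors of exact integrals) carry real margin.

Standard errors for weighted observables come from a delete-one-iteration
jackknife in which the density surface is *re-estimated for every
replicate* (`reweighted_observables()`). A weight-based standard error
conditional on the estimated surface misses the dominant uncertainty — the
zone-mass estimate itself — and is anti-conservative.

## The synthetic binding ensemble

`generate_binding_ensemble()` emulates, with known ground truth, the
statistical structure that the analysis layer measures on a real weighted
ensemble: a pseudo-atomic receptor (transmembrane alignment bundle, an
11-bead disordered N-terminal tail rooted at the pocket gate, four contact
side-chain nitrogens) and a 14-heavy-atom rigid-core ligand. Per snapshot:

* the ligand centroid comes from a two-component mixture — a pocket
  Gaussian (weight 0.35, sigma 3 Å) and a diffuse shell (radii 5–62 Å) —
  so all thirteen 5 Å slices of the `r_bb` axis are populated;
* each tail bead is placed in or out of ligand contact by a Bernoulli draw
  from the 13 × 11 slice-by-residue probability table; the default table
  moves the contact site from the tail tip (slices 5–7) to the tail root
  (slices 3–4) as the ligand approaches, with a weak residual contact of
  the Arg-like bead at the pocket bottom;
* the rigid ligand is rotated about its centroid by a composition of three
  random-axis rotations with wrapped-Gaussian angles of width
  `1/sqrt(3 kappa)`; `kappa` is 50 inside the gate (`r_bb` < 20 Å) and 0.05
  outside. A single rotation from a reference pose cannot randomize an
  orientation completely (the averaged rotation matrix tends to I/3);
  composing three pushes the kappa → 0 limit of the averaged vector norm
  below 0.05, which is what "orientationally disordered" needs to mean for
  the recovery tests. Only the limits and monotonicity of this noise model
  are relied on;
* the four native-contact indicators are independent Bernoulli draws from
  logistic formation curves in `r_bb`, realized *geometrically*: the
  receptor nitrogens are placed so that the minimum heavy-atom distance
  criterion reproduces each drawn indicator exactly (the sulfonamide
  nitrogen and the sulfonyl oxygens sit on opposite ends of the toy ligand
  precisely so that the two contacts sharing the Lys182 nitrogen can be
  realized in all four joint states).

What passing these tests shows — and does not show — about real data: the
generator produces geometrically consistent coordinates, so the analysis
operations are exercised end to end (superposition, distance criteria,
binning, weighting), but the pseudo-structures carry no excluded volume, no
chain connectivity of the tail, no force-field physics and no coupling
between the latent draws beyond what is stated above. Recovery of the
planted parameters validates the estimators, not the realism of any
particular molecular system.

## Analysis conventions

* Cube fields use 3 Å cubes in the receptor-superposed frame; superposition
  is a proper Kabsch fit on the alignment group only, never on the ligand.
  Density fields are max-normalized by default so contour levels like
  0.5 / 0.1 / 0.01 are directly meaningful; raw probability mass is
  available via `normalize = "prob"`.
* `r_bb` slices are half-open, `[5(k-1), 5k)`, so an exact multiple of 5 Å
  belongs to the upper slice; with the default 13 slices the 4|5 boundary
  is the pocket gate.
* Contact criteria are minimum heavy-atom distances below 5.0 Å throughout
  (tail, membrane slab and native contacts alike); hydrogens are excluded
  by element, with a name-prefix fallback.
* Potentials of mean force are `-RT ln p` with RT from CODATA constants at
  the configured temperature (0.5962 kcal/mol at 300 K). Empty cells,
  slices, cubes and windows are flagged `NA`, never zero-filled: the PMF of
  an unsampled bin is undefined, not large-finite.
* `P_RDF` is `P_DDF / (4 pi R^2)` renormalized at bin centres — a
  shell-volume correction consistent with the expected peak ordering
  (RDF peak below DDF peak); it is a convention of this package, not a
  reproduction of any particular published definition.
* Scalar-product fields are flagged undefined where the averaged-vector
  norm falls below 0.3, the conventional display floor.
* Native-contact windows are `[r_bb - 0.25, r_bb + 0.25]` Å with centres
  every 0.5 Å from 0.25 Å; the weighted mean and standard deviation of the
  0–4 contact count are reported per window.

## Numerical choices and degenerate inputs

Intra-zone binning clamps to the zone box; membership uses half-open
intervals with the last interval closed, so axis coverage has no gaps and
overlap regions give deliberate multiplicity. Transition draws with all
candidate densities zero keep the walker in place. `update_q` carries
zones with zero counts through unchanged (up to the global
renormalization). The GA discards non-finite candidates in favour of the
elite. Collinear superposition fit sets, coincident orientation anchors,
empty atom selections after hydrogen filtering, and RC values outside the
zone coverage all raise informative errors rather than propagating NaNs.

## Known limitations

The engine couples only to the bundled analytic backends; driving a real MD
engine is out of scope. The exact transition-probability formula and the
exact convergence diagnostic of the originating method are published only in
supplementary material not available here; the implementations above are
stated decisions validated by the canonical-recovery property, not claimed
reproductions. Cube fields live on an axis-aligned grid, so exact
rigid-motion invariance holds for grid-free statistics and for translations
of the fitted grid, but a rotation re-bins the field. The zone-visit
flattening is exact only for in-box dwell time under soft walls. Finally,
the headline biological results of the motivating study (220 µs of all-atom
membrane MD) are far beyond desk scale; everything here is verified on toy
potentials and synthetic ensembles with known ground truth.
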
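# zonesampler

Zone-based virtual-system coupled sampling and weighted-ensemble binding
analysis in R.

## What problem this package addresses

Ligand–receptor binding of flexible molecules spans free, intermediate and
bound states separated by free-energy barriers that ordinary simulation
cannot cross on accessible time scales. A family of generalized-ensemble
methods attacks this in a low-dimensional space of reaction coordinates
(RCs) — here, distances λ between centroids of named atom groups — by
dividing each RC axis into small *overlapping zones* and confining the
system to one zone at a time with a flat-bottom restraint. At a fixed cadence
Δτ the system may hop to any zone containing its current λ, with probability
driven by the running estimate of the canonical RC density
Q<sub>cano</sub>(λ). Iterating sample → histogram update → genetic-algorithm
smoothing across zone seams → per-zone convergence check (E<sub>local</sub>
< 0.25) expands the sampled region until Q<sub>cano</sub> is determined
everywhere; a thermodynamic weight ∝ Q(cell)/n(cell) then turns the pooled
snapshots into a canonical (300 K) ensemble, from which any equilibrium
observable follows.

On top of the weighted ensemble the package computes the binding statistics
used to dissect a ligand-capture pathway: 3 Å-cube spatial densities
ρ(r<sub>cube</sub>) of group centroids, cube-based contact-ratio fields
c̄(r<sub>cube</sub>), slice-resolved residue-contact free energies
F<sup>Δk</sup>(j) = −RT ln ρ<sub>cnt</sub><sup>Δk</sup>(j), per-slice
atom–residue contact maps θ<sup>Δk</sup>(i,j), minimum-distance PMFs
PMF<sub>Δk</sub>(r<sub>b−N</sub>) = −RT ln P, averaged orientation-vector
fields v̄(r<sub>cube</sub>) and their scalar products SP against a reference
pose, native-contact profiles N<sub>cnt</sub>(r<sub>bb</sub>) with a 5.0 Å
formation criterion on 0.5 Å windows, RMSD distance/radial distributions,
and a Henderson–Hasselbalch protonation helper. Every component is
verifiable at desk scale on analytic toy potentials (with quadrature ground
truth) and on synthetic weighted ligand–receptor ensembles with planted
parameters. The intended users are method developers and simulation
scientists who need a transparent, testable reference implementation of the
zone-sampling machinery and its analysis layer.

## Worked example

```r
library(zonesampler)

## production-schedule bookkeeping (2 fs steps, 2000 runs x 1e6 steps,
## snapshot every 1e5 steps, 55 iterations)
sched <- plan_schedule(engine_config(), iterations = 55)
cat(sprintf("aggregate time per iteration: %.1f us; total: %.1f us; snapshots: %g\n",
            sched$iteration_time_us, sched$total_simulated_time_us,
            sched$total_snapshots))
#> aggregate time per iteration: 4.0 us; total: 220.0 us; snapshots: 1.1e+06

## protonation state of a weak acid (pKa 5.1) at blood pH
cat(sprintf("neutral fraction at pH 7.4 (pKa 5.1): %.1f%%\n",
            100 * neutral_fraction(5.1, 7.4)))
#> neutral fraction at pH 7.4 (pKa 5.1): 0.5%

## synthetic weighted binding ensemble with known ground truth
gen <- generate_binding_ensemble(synthetic_ensemble_spec(n_snapshots = 5000,
                                                         seed = 42))
ens <- align_ensemble(gen$ensemble)

## residue-contact free energies F = -RT ln rho per 5 A slice of r_bb
rc <- residue_contact_pmf(ens)
round(rc$F[3:7, c("Ser80", "Arg83", "Ile85", "Pro89")], 2)
#>        Ser80 Arg83 Ile85 Pro89
#> slice3  1.28  1.71  0.08  0.09
#> slice4  1.03  1.80  0.10  0.09
#> slice5  0.18  0.22  1.22  1.09
#> slice6  0.19  0.22  1.18  1.09
#> slice7  0.18  0.19  1.12  1.24

## native-contact formation profile near the bound pose
head(native_contact_profile(ens), 3)
#>   r_bb    n_cnt    sd_cnt n_snapshots
#> 1 0.25 4.000000 0.0000000           1
#> 2 0.75 3.076923 0.8284869          13
#> 3 1.25 2.263158 0.9647528          38
```

The F matrix reads like a free-energy landscape over (tail residue, r_bb
slice): in slices 5–7 (outside the pocket gate at 20 Å) the tail *tip*
residues Ser80–Arg83 hold the ligand (low F ≈ 0.2 kcal/mol), while in
slices 3–4 (inside the pocket) the contact has slid to the *root* residues
Ile85–Pro89 — the planted tip-to-root sliding of the generator, recovered
by the analysis. The contact count climbs toward 4 as r_bb → 0.

The sampler itself is driven either from R (`validate_config()`,
`run_sampling_loop()`, `reweighted_observables()`) or from the shell via the
thin CLI:

```sh
Rscript inst/cli/zonesampler.R sample --config run.yaml
Rscript inst/cli/zonesampler.R analyze --config run.yaml
```

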
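# emt4d — energy/mass transfer mapping for online 4D dose reconstruction

`emt4d` accumulates radiotherapy dose delivered on moving, deforming anatomy
(phase-binned 4D image sets, e.g. lung under respiration) onto a common
reference phase. It is written for medical-physics users who need a fast,
conservation-exact dose-warping engine and a fully synthetic test bed for it.

## Method

Dose warping must decide what happens when deformation compresses several
source voxels into one reference voxel. **Energy/mass transfer (EMT)**
mapping resolves the ambiguity physically: each image voxel carries energy
*E*<sub>T</sub> = *d*·*m* (its sampled phase dose times its mass
*m* = ρ·*V*<sub>A</sub>) and mass *m*; both are transported separately along
the displacement vector field and the accumulated dose is the per-voxel
quotient *D* = *E*/*M*. The alternative **direct dose mapping (DDM)**
baseline averages contributing dose values instead; under compression EMT is
the mass-weighted mean and DDM the plain mean, and the two disagree in
heterogeneous, steep-gradient regions.

A displaced voxel centre generally falls between reference voxel centres,
so each transfer is distributed to the 8 surrounding voxels with trilinear
overlap weights Δ*E*<sub>j</sub> = V̄<sub>j</sub>·*E*<sub>T</sub>, where the
V̄<sub>j</sub> are products of per-axis factors
(Δx̄<sub>i</sub>, 1 − Δx̄<sub>i</sub>) of the relative offset
Δx̄<sub>i</sub> ∈ (−0.5, 0.5]. The offsets are stored as signed 8-bit codes
(dequantized by 2⁷ − 1) in compact displacement-vector-structure (DVS)
records of 7–8 bytes, compiled in three equivalent layouts:

* **push** — serial scatter in source order (8-byte records with a status
  byte),
* **pull** — records re-keyed per reference voxel; evaluated as a race-free
  per-voxel gather whose result is bitwise independent of the z-slab
  decomposition (7-byte records),
* **unified** — records keyed by the minimum-index overlap corner with
  branch-free weight factors w⁰ / w⁺ = 1 − w⁰, the form a vectorising
  compiler wants.

All three evaluate identical arithmetic and differ only in summation order;
the package verifies their equivalence numerically. A seeded synthetic 4D
phantom (lung-like anatomy, analytic invertible respiratory deformation,
tracked Gaussian beam, elliptical 25 Hz target trace) and a simulated
online reconstruction loop make the whole method testable with no external
data.

## Worked example

Accumulate one delivered breathing cycle of the default phantom (10 phases,
64×64×40 image grid at 1×1×2 mm, 32×32×40 dose grid at 2×2×2 mm):

```r
library(emt4d)

spec    <- phantom_spec(seed = 1)
al      <- grid_alignment(spec$image_grid, spec$dose_grid)
ref     <- generate_reference(spec)
phases  <- lapply(0:(spec$n_phases - 1), generate_phase, spec = spec,
                  reference = ref)
bundles <- precompute_phase_bundles(phases, al, layout = "unified")

state <- run_reconstruction(reconstruction_config(
  bundles, al,
  trace         = generate_trace(spec, spec$breathing_period_s),
  centroids     = phase_centroids(spec),
  dose_provider = function(phase, tick) generate_tick_dose(spec, phase, tick),
  method = "emt", layout = "unified"))

summarize_reconstruction(state)
#>         min_gy    mean_gy    max_gy n_ticks floored_voxels excluded_records
#> 1 5.490251e-20 0.01066635 0.9088264     101          19456           139240
```

The 101 ticks (40 ms each over one 4 s cycle) deliver a peak accumulated
dose of about 0.91 Gy where the tracked beam follows the tumour;
`floored_voxels` counts voxel-ticks whose transferred mass fell below the
10⁻⁶ g floor (dose defined as 0 there) and `excluded_records` the per-phase
displacement records whose 8-voxel overlap set left the reference grid and
were dropped rather than clipped, keeping energy conservation exact.

A thin command-line front end wrapping the same functions ships in
`inst/cli/emt4d.R` (`phantom`, `compile`, `map`, `reconstruct`
subcommands).

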
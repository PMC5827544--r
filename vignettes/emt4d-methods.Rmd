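---
title: "Energy/mass transfer dose accumulation: model, data structures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy/mass transfer dose accumulation: model, data structures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emt4d)
```

## The problem

In 4D radiotherapy of moving organs such as lung, dose is delivered while the
anatomy cycles through respiratory states. To judge what was actually
delivered, the per-phase dose must be accumulated onto one reference anatomy.
A displacement vector field (DVF), typically produced by deformable image
registration, maps each moving-phase voxel centre to a point in reference
space. Because tissue deforms, several source voxels can land in one
reference voxel, and any accumulation scheme must decide what happens there.

*Direct dose mapping* (DDM) averages the dose values of the contributing
source voxels. *Energy/mass transfer* (EMT) mapping instead transports the
physical quantities that define dose: each image voxel carries energy
$E_T = d \cdot m$ (its sampled dose times its mass $m = \rho V_A$, with
$\rho$ from the CT number and $V_A$ the voxel volume) and mass $m$; both are
scattered to the reference grid and the accumulated dose is the per-voxel
quotient $D = E/M$. Under compression EMT therefore forms the mass-weighted
mean of the contributing doses, while DDM forms their plain (weight-averaged)
mean; with masses $(0.001, 0.003)$ g and doses $(1, 2)$ Gy collapsing into
one voxel, EMT gives $1.75$ Gy and DDM $1.5$ Gy. The package implements EMT
as its core method and DDM as a baseline that shares the same geometric
weights, so the two differ only in the averaging-vs-transport decision.

## Geometry and the overlap weights

Volumes live on rectilinear, mutually aligned grids. The image (and DVF) grid
is finer than the dose/energy grid by an integer per-axis ratio — clinically
$2 \times 2 \times 1$ image voxels per dose voxel for
$1 \times 1 \times 2$ mm images and $2 \times 2 \times 2$ mm dose — and the
phase dose is sampled piecewise-constant: an image voxel takes the dose of
the coarse voxel that contains it. No interpolation of the dose cube is
performed; the containing-voxel rule keeps block sums exact and matches the
overlap picture of the fine/coarse grid relation. Integer ratios are
enforced; oblique or sheared acquisitions are out of scope.

A displaced point rarely coincides with a reference voxel centre. In
reference-voxel units, let $\Delta\bar{x}_i \in (-0.5, 0.5]$ be the offset of
the target point from its nearest voxel centre. A unit virtual voxel centred
at the point overlaps up to $2^3 = 8$ reference voxels; each one's share is
the overlap volume, a product of per-axis factors drawn from
$(\Delta\bar{x}_i,\, 1 - \Delta\bar{x}_i)$ according to the offset's sign.
The weights are non-negative and always sum to one, so scattering
$E_T$ with them conserves energy exactly. `overlap_weights()` implements
this; `box_intersection_oracle()` recomputes it in tests by explicit
axis-aligned interval intersection, sharing no code with the kernel path.

## The DVS record and quantization

Per displacement, only a voxel index and the three offsets are needed. The
offsets are stored as signed 8-bit integers with
$\Delta\bar{x}_i = \Delta X b_i / (2^7 - 1)$, i.e. codes in $[-127, 127]$ at
a worst-case round-trip error of $1/254 \approx 0.4\%$ of a voxel — small
against registration uncertainty, and an 8-fold reduction over a float
triple. Quantization rounds half away from zero so the code's sign always
equals the offset's sign, which is what selects the overlap octant. The
literal $2^7-1$ divisor is kept even though offsets only occupy
$[-0.5, 0.5]$; rescaling the code range would change the published
dequantization law for a factor-of-two precision gain the method does not
need. A record is 8 bytes in the push layout (4-byte index, 3 offset bytes,
1 status byte) and 7 bytes in the pull/unified layouts, against 80 bytes per
displacement for a naive uncoupled sparse-matrix alternative (10-byte
element for each of the 8 overlap targets).

Half-integer ties are broken at compile time so the stored offset is always
in $(-0.5, 0.5]$: a point exactly between two voxel centres stays with the
lower-index voxel at offset $+0.5$. This makes compilation deterministic and
order-independent.

Records whose full 8-voxel overlap ensemble leaves the reference grid are
excluded (flagged unused) rather than clipped. Clipping would silently lose
energy and break the conservation invariant; exclusion keeps conservation
exact for everything that is mapped, and the excluded count is logged so the
choice is auditable. The count is determined from the *quantized* offsets —
the same values the kernels will use — so compile-time and run-time
ensembles agree exactly.

## The three layouts

**Push** iterates source records in ascending image-voxel order and scatters
each $E_T$ to its 8 overlap voxels — the natural serial arrangement.

**Pull** re-keys the used records per reference voxel (ascending source index
within a voxel). The package evaluates it as a true gather: each reference
voxel independently collects the contributions of records keyed to its
neighbourhood, in a canonical order (ascending key voxel, then source
index). Every voxel is written by exactly one worker, so the arrangement is
race-free without atomics, locks, or halo buffers, and the result is
*bitwise* independent of how the z-extent is decomposed into slabs
(`n_slabs` only partitions the loop). An alternative considered was to let
each slab scatter into private halo planes that are merged afterwards; that
variant cannot be bitwise slab-count-invariant, because merging summed halo
buffers changes the floating-point association at slab boundaries, so the
gather formulation was adopted.

**Unified** removes the sign-dependent branching from the weight evaluation.
Records are re-keyed by the minimum-index corner ("voxel 1") of their
overlap ensemble and store three weight factors $w_i^0$ instead of offsets:
$w_i^0 = |\Delta\bar{x}_i|$ if the offset is negative, else
$1 - \Delta\bar{x}_i$. Voxel 1's share is $w_1^0 w_2^0 w_3^0$ and a $+1$
step along axis $i$ swaps $w_i^0$ for $w_i^+ = 1 - w_i^0$; the 8 weights are
one fixed pattern of products, the form a vectorising compiler can evaluate
without conditionals.

A deliberate precision choice: $w^0$ is computed from the *dequantized*
offset, which makes it an exact multiple of $1/127$ in $[0,1]$, so its own
8-bit quantization is lossless and the unified layout reproduces the push
layout's weights identically. Deriving $w^0$ from the unquantized offset and
quantizing afterwards would inject a second, independent rounding and the
layouts would no longer compute the same numbers.

Because all three layouts evaluate identical per-contribution arithmetic,
they differ only in summation order. At double precision the mean per-voxel
relative deviation between layouts on the default phantom is at the
$10^{-15}\,\%$ level; a single-precision accumulation mode is provided to
study the same reordering effect at float resolution, where deviations reach
the $10^{-5}\,\%$ scale. These deviations are measured by
`layout_equivalence_study()` and bounded in the test suite; per-tick
wall-clock latency is logged by the reconstruction loop but never asserted,
since it is a property of the host hardware.

## Division, the mass floor, and degenerate voxels

Accumulated dose is $D = E/M$ per reference voxel. Where the transferred
mass is below `mass_floor` (default $10^{-6}$ g, roughly a thousandth of a
water-density image voxel) the dose is defined as zero and the voxel is
counted; the count is reported so near-empty regions are visible rather than
silently amplified. The floor only matters where essentially no tissue was
transported — typically outside the mapped region or at the excluded
boundary shell.

## The DVS container

The `.dvs` file is little-endian with a fixed 32-byte header (magic,
version, layout tag, record count, image and reference shapes). Push files
are exactly header + $8N$ bytes. Pull/unified files store the
per-reference-voxel record ranges — bookkeeping that belongs to the
reference grid, scaling with voxel count, not with displacement count — as a
4-byte-per-voxel index section between header and records; the record
payload itself is exactly $7N$. Flat voxel indices are 0-based, axis 1
fastest, 32-bit unsigned.

## The synthetic phantom

The phantom emulates a phase-binned 4D lung set so the whole pipeline is
testable without patient data:

* **Anatomy** — soft tissue (0 HU) containing an ellipsoidal low-density
  lung ($-700$ HU) with a spherical soft-tissue tumour, plus seeded Gaussian
  HU noise (sd 15 HU).
* **Motion** — a superior–inferior compression field
  $u(z) = A \sin(\pi z / L)\, s_i\, \hat{z}$ with per-phase scale
  $s_i = \sin(2\pi i / P)$, $P = 10$ phases by the phase-binning convention,
  and default amplitude $A = 8$ mm, a typical lung tumour excursion. The
  profile vanishes at both z faces and the Jacobian
  $1 + A s \pi/L \cos(\pi z/L)$ stays positive for all defaults, so the map
  is invertible; the inverse is found by fixed-point iteration to
  $10^{-3}$ voxel. Phase 0 has $s = 0$ and is the reference. The
  compressing half of the cycle produces genuine many-to-one mappings, which
  is what separates EMT from DDM.
* **Delivery** — an isotropic Gaussian beam ($\sigma = 6$ mm, peak
  0.01 Gy per tick) that tracks the phase target position, standing in for
  the dose-influence-matrix dose engine, which is out of scope here.
* **Trace** — an elliptical target trajectory (semi-axes 2, 1, 8 mm; the z
  semi-axis matches the tumour-centre excursion) sampled every 40 ms, one
  breathing cycle per 4 s.

Default grids are $64 \times 64 \times 40$ image voxels at
$1 \times 1 \times 2$ mm against $32 \times 32 \times 40$ dose voxels at
$2 \times 2 \times 2$ mm — the clinical grid relation at reduced extent, so
a full breathing cycle accumulates in seconds on one core; clinical sizes
remain reachable through `phantom_spec()`. The phantom does **not** emulate
realistic CT texture, MLC aperture shapes, breathing hysteresis or
registration error: passing tests demonstrate the correctness of the
mapping machinery on controlled deformations, not the clinical accuracy of
any particular DVF.

## The reconstruction loop

Per 40 ms tick: the respiratory phase is chosen as the nearest phase
centroid to the current target position (ties to the lower index, whole-tick
phase assignment — sub-tick phase changes are not modelled); the tick's
phase dose cube is fetched; energy is mapped with the configured layout; and
the increment $E/M_{\text{phase}}$ is added to the accumulated dose. The
transferred mass is a per-phase geometric quantity, so it is precomputed
once per phase and cached with the compiled DVS table; dose additivity then
makes the accumulation linear in the delivered dose and invariant to
reordering ticks within a phase. Conservation residuals, floored-voxel and
excluded-record counts, and per-tick latency are logged with every run.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 1)
al <- grid_alignment(spec$image_grid, spec$dose_grid)
ref <- generate_reference(spec)
phases <- lapply(0:(spec$n_phases - 1), generate_phase, spec = spec,
                 reference = ref)
bundles <- precompute_phase_bundles(phases, al, layout = "unified")
state <- run_reconstruction(reconstruction_config(
  bundles, al, generate_trace(spec, spec$breathing_period_s),
  phase_centroids(spec),
  function(phase, tick) generate_tick_dose(spec, phase, tick),
  method = "emt", layout = "unified"))
summarize_reconstruction(state)
```

## Known limitations

Voxels are transported as rigid translations; rotation or deformation of an
individual voxel is not modelled, consistent with the small-voxel
approximation. DVFs are inputs — the package performs no registration and
inherits whatever error the registration carries. Dose sampling is
piecewise-constant from the coarse grid. Boundary records are excluded, so
the outermost reference shell accumulates no dose from near-edge sources.
The `.dvs` container limits grid axes to 65535 voxels and record counts to
32-bit range.
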
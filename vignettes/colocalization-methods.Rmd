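---
title: "Measuring Golgi-to-ER enzyme relocation: models and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Golgi-to-ER enzyme relocation: models and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galacoloc)
```

## Why this package exists

Partial relocation of a Golgi enzyme into the endoplasmic reticulum is easy
to miss and easy to over-interpret. The enzyme starts in a compact, bright
perinuclear compartment and redistributes into a reticular compartment at
least five times larger, so the relocated pool is diluted to a small
fraction of the Golgi's per-pixel brightness. Three analysis decisions
determine whether the relocation is detected at all:

1. **Threshold choice.** Automatic joint thresholding (Costes) places the
   threshold where the two channels' below-threshold pixels decorrelate.
   When one population of pixels is bright and correlated (Golgi) and
   another dim and uncorrelated with the Golgi marker (relocated enzyme in
   the ER), the scan terminates near the bright population and the dim
   signal is excluded. A fixed per-channel threshold calibrated on
   background keeps it.
2. **Direction of the Manders coefficient.** $M_2$, the fraction of Golgi
   marker covered by enzyme, is unchanged by relocation as long as *some*
   enzyme remains at the Golgi, because Manders coefficients are
   intensity-insensitive by construction. $M_1$, the fraction of enzyme
   signal at the Golgi, falls approximately linearly in the relocated
   fraction.
3. **Masking the dominant pool.** Against an ER marker that covers most of
   the cell, whole-cell coefficients barely move. Zeroing the enzyme inside
   the Golgi-marker mask first, then computing per-cell coefficients
   between the remaining enzyme and the ER marker, isolates exactly the
   signal that relocated.

The package implements all of these (plus object-based colocalization for
punctate compartments and per-cell intensity readouts) and a simulator
whose ground truth makes each claim checkable.

## The synthetic field model

`simulate_field()` renders fields of HeLa-like cells placed on a jittered
grid (no overlap, so nuclei counting and region assignment are
unambiguous). Per cell:

* a circular cell body (radius 26 px at 0.1 µm/px) and a nucleus
  (0.38 × cell radius, slightly offset);
* a **Golgi**: a crescent hugging the nucleus (ring 1–7 px from the nuclear
  rim, ±55°), area ≤ 10% of the cell — a compact, concentrated compartment;
* an **ER**: a reticular network rendered by thresholding smoothed Gaussian
  noise inside the cytoplasm at its 40th percentile, excluding nucleus and
  Golgi. This guarantees er_area ≥ 5 × golgi_area without claiming
  biological realism of the geometry — what matters for the analysis
  questions is *dispersed, dim, large*.

The enzyme channel carries a per-cell photon budget
$T_c = \mathrm{golgi\_peak} \times \mathrm{golgi\_area}_c$ split as
$(1-f)\,T_c$ uniformly over the Golgi and $f\,T_c$ uniformly over the ER.
The budget is conserved exactly across $f$: relocation moves signal, never
creates or destroys it, so the ER per-pixel intensity is diluted by the
area ratio (about 3% of Golgi brightness at $f = 0.3$). The glycan (Tn)
channel is a Golgi baseline plus $g \cdot f \, T_c$ on the ER template —
the substrate-abundance gain $g$ (default 8) models how a small relocated
enzyme pool yields a large Tn increase.

Acquisition is modelled in `apply_optics()`: optional lateral/axial
Gaussian blur, per-slice photobleaching (slice $k$ in acquisition order
attenuated by $(1-b)^k$, identically across channels — the simplest serial
confocal model), then Poisson photon noise, additive Gaussian read noise
(sd 2), rounding and clipping to the bit depth.

For z-stacks the Golgi is axially compact (Gaussian z-profile, σ = n_z/12
slices) while each ER pixel occupies a band of 40% of the stack centred
near the cell mid-plane with per-pixel jitter; nuclei span all slices.
Photon budgets are conserved in 3-D, so sectioning a 61-slice stack
dilutes the ER enzyme to a few counts per voxel — which is precisely why
per-slice bleaching pushes it below a fixed detection threshold while the
Golgi pool persists. This is the mechanism the bleaching benchmark
measures.

Defaults worth knowing (all in `simulation_params()`):

| parameter | default | meaning |
|---|---|---|
| `n_cells` | 20 | cells per field (the benchmark condition size) |
| `relocation_fraction` | 0 | fraction $f$ of enzyme budget moved to the ER |
| `tn_gain` | 8 | glycan signal per unit ER-resident enzyme |
| `golgi_peak` | 3000 | Golgi enzyme intensity (16-bit scale) |
| `er_peak` | 300 | ER-marker brightness (dim vs Golgi) |
| `poisson_noise`, `read_noise_sd` | on, 2 | camera model |
| `psf_sigma_xy`, `psf_sigma_z` | 0 | blur is opt-in |
| `n_z_slices`, `bleach_rate` | 1, 0 | sectioning/bleaching opt-in |

PSF blur defaults to off: fields are rendered at the target resolution and
noise is the modelled acquisition artifact. This keeps mask-based photon
bookkeeping exact (the ground-truth invariants and the relocation-recovery
benchmark are then sharp); enabling blur spreads a few percent of Golgi
signal across the mask boundary and biases mask-based readouts
accordingly, which is worth knowing when interpreting real data too.

What the simulator does **not** emulate: spectral bleed-through, a
calibrated PSF, absolute intensities of any particular microscope,
cell-to-cell expression variability beyond geometry, or live-cell
dynamics. Passing benchmarks here shows the *analysis logic* behaves as
claimed under a controlled model — not that any specific real dataset will
show a given effect size.

## Numerical and design choices

* **Strict comparisons everywhere.** Binarization and Manders numerators
  use strict `>`; object matching uses strict `<` on centroid distance.
  One convention, fixed, so results are bit-reproducible.
* **Fixed-threshold default**: mean + 2 SD of a background region
  (extracellular pixels in simulations); real data should supply
  per-channel constants. Every result records the thresholds used.
* **Costes scan**: total-least-squares regression, unit candidate steps on
  the native integer scale, descending from `max(A)`; the first candidate
  whose below-threshold Pearson is ≤ 0 wins. If the correlation never
  reaches zero (e.g. perfectly correlated channels) the minimum positive
  candidate is returned flagged `converged = FALSE`. The implementation
  reduces the scan to prefix sums over pixels ordered by
  $\max(A_i, (B_i - c)/a)$, making the exhaustive unit scan exact and fast.
* **Thresholded Manders** (own-channel threshold in the numerator) is the
  default, matching the fixed-thresholds-on-both-channels workflow; the
  classic variant is available via `thresholded = FALSE`.
* **Undefined values propagate.** Empty supra-threshold denominators yield
  `NA` with a `*_defined` flag and are excluded from condition means with
  counts reported. Silent zeros would bias fold changes toward the null.
* **Per-cell regions** are nuclei-seeded Voronoi partitions
  (`segment_cells()`), a reproducible stand-in for manual cropping;
  simulations can use ground-truth cell masks directly.
* **Object detection**: 8-connected components (EBImage's 4-connected
  labelling plus a union-find merge of diagonal adjacencies), minimum area
  4 px, intensity-weighted sub-pixel centroids, 0-based (y, x) pixel
  coordinates. Matching is non-exclusive (a reference object may satisfy
  several query objects), the simplest reading of the distance criterion;
  the matching radius comes from the Rayleigh criterion
  (`rayleigh_resolution_px()`) when optics metadata exists, otherwise it
  must be given explicitly.
* **Projection vs z-stack**: coefficient workflows default to maximum
  projections; the full-voxel path is available (`use_projection = FALSE`)
  and recorded in the output. Projections are computed on raw intensities,
  with no background subtraction beforehand.
* **"Count × mean" intensity readouts** are implemented as the
  supra-threshold intensity sum (the two are identical), the only
  per-image-well-defined reading.
* **Paired t tests** use Student's t on paired differences via
  `stats::t.test`; zero-variance differences raise an error rather than
  returning a p-value.

## Benchmark sizes

The shipped checks use: 20 cells per condition for the directionality
sweep ($f \in \{0, 0.1, 0.2, 0.3\}$) and the masked-ER fold change; 20
seeded replicates of 6-cell fields for the Costes comparison; 4-cell,
61-slice stacks for the bleaching contrast ($b = 0$ vs $0.02$); 8-cell
fields over $f \in \{0.1, \dots, 0.5\}$ × 10 seeds for relocation
recovery; and 1000 random small images for brute-force oracle equivalence
of Manders, Pearson, projection, object matching and masked totals. These
sizes give stable statistics at interactive runtimes; all scale with the
parameters if larger studies are wanted.

## Known limitations

* The Costes implementation targets the thresholding behaviour, not the
  randomization significance test from the same lineage.
* Object colocalization is 2-D (projections); no 3-D matching or
  overlap-area variant.
* The simulator's ER geometry is a statistical texture, not a membrane
  model; per-cell brightness is homogeneous apart from geometry.
* `normalize_to_control()` divides by the control *mean*; with small
  control samples the resulting fold distribution is correlated across
  conditions, which the paired tests on raw values avoid.
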
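# galacoloc

Colocalization analysis for Golgi-to-ER relocation of glycosylation enzymes.

## The problem

GALNTs (polypeptide GalNAc-transferases) normally reside in the Golgi. Under
growth-factor signalling they partially relocate to the endoplasmic
reticulum, where abundant substrates drive a large increase in Tn glycan
levels (the GALA phenotype). Detecting this relocation in fluorescence
microscopy is an image-analysis problem with traps: only a minority of the
enzyme moves, and it moves from one bright compact organelle into a dim
compartment spread over most of the cell. Whether an analysis sees the
relocation depends on how it thresholds and which direction of
colocalization it measures.

`galacoloc` implements the analysis choices that matter, side by side, so
each can be benchmarked against a synthetic ground truth:

* **Directional Manders coefficients** with explicit fixed thresholds.
  For channels $A$ (enzyme) and $B$ (Golgi marker) with thresholds
  $T_A, T_B$:

  $$M_1 = \frac{\sum_i A_i \,[A_i > T_A][B_i > T_B]}{\sum_i A_i\,[A_i > T_A]},
    \qquad
    M_2 = \frac{\sum_i B_i \,[A_i > T_A][B_i > T_B]}{\sum_i B_i\,[B_i > T_B]}$$

  $M_1$ (fraction of enzyme at the Golgi) falls as enzyme relocates;
  $M_2$ (fraction of Golgi marker covered by enzyme) barely moves, because
  enzyme remains at the Golgi and Manders coefficients are insensitive to
  intensity changes. Quantifying relocation with $M_2$ alone misses it.
* **Costes automatic thresholding**, for comparison: thresholds descend
  along the channels' orthogonal regression line until the below-threshold
  pixels decorrelate. With a dim dispersed signal this settles near the
  bright population and excludes the dim signal from analysis.
* **Golgi-mask removal**: zero the enzyme inside the Golgi-marker mask, then
  compute per-cell Manders against an ER marker — the workflow that makes a
  small relocated fraction measurable.
* **Object-based colocalization** of punctate channels (e.g. ERGIC53 vs
  GALNT): intensity-weighted centroids of discrete objects, matched when
  their distance is strictly below the microscope resolution.
* **Per-cell intensity quantification**: supra-threshold totals normalized
  by nuclei count, Golgi-region signal per cell, fold changes with
  two-tailed paired t tests.
* **A synthetic field generator** with known relocation fraction `f`,
  per-compartment ground-truth masks and photon budgets, Poisson + read
  noise, optional z-sectioning and per-slice photobleaching.

## Worked example

Simulate 20 cells with 30% of the enzyme relocated, then run the analyses:

```r
library(galacoloc)

params <- simulation_params(n_cells = 20, relocation_fraction = 0.3, seed = 1)
sim <- simulate_field(params)
sim$stack
#> image_stack: 256 x 320 px, 1 z-slice(s), 5 channel(s), 16-bit
#>   roles: nuclei, golgi_marker, er_marker, enzyme, glycan
#>   pixel size: 0.1 um/px

proj <- max_project(sim$stack)
bg <- !truth_mask(sim$truth, "cell")            # extracellular region
t_enz <- background_threshold(channel_image(proj, "enzyme"), bg)
t_gm  <- background_threshold(channel_image(proj, "golgi_marker"), bg)
t_er  <- background_threshold(channel_image(proj, "er_marker"), bg)

m <- manders(channel_image(proj, "enzyme"),
             channel_image(proj, "golgi_marker"), t_enz, t_gm)
c(M1 = m$m1, M2 = m$m2)
#>    M1    M2
#> 0.712 0.999
```

With 30% of the enzyme relocated, `M1` has dropped to 0.712 (≈ 1 − f) while
`M2` still reads 0.999 — the directionality trap in one line. The mask
removal workflow then shows where the relocated enzyme went:

```r
er <- er_coloc_after_golgi_removal(
  sim$stack, c(enzyme = t_enz, golgi_marker = t_gm, er_marker = t_er),
  sim$truth$cell_labels)
mean(er$m2[er$m2_defined])
#> [1] 0.958    # out-of-Golgi enzyme blankets the ER marker; ~0.04 at f = 0

gmask <- fixed_threshold(channel_image(proj, "golgi_marker"), t_gm)
estimate_relocation_fraction(channel_image(proj, "enzyme"), gmask,
                             background = median(channel_image(proj, "enzyme")[bg]))
#> [1] 0.291    # recovers the true f = 0.3
```

A command-line interface wraps the same functions
(`system.file("cli", "gala-coloc.R", package = "galacoloc")`):

```sh
Rscript gala-coloc.R simulate --config cfg.yaml --out field.tif --truth truth.json
Rscript gala-coloc.R coloc    --config cfg.yaml --in field.tif --out coloc.csv
```

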
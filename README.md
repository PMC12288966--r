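# nucmorph

Nuclear morphometry for fluorescence stacks and histology planes: how big are
nuclei, how crowded are they, and how strongly is a nuclear-envelope protein
enriched at the nuclear periphery?

The package re-implements, as tested and reusable R code, the imaging-analysis
chain used to study oncogene-driven nuclear size changes in pancreatic cancer
models: oncogenic KRAS shrinks nuclei (and cells), and the inner-nuclear-
membrane protein Emerin redistributes toward the nuclear periphery. Every
stage is exercised against a synthetic-microscopy generator with exact
analytic ground truth, so the whole pipeline is testable without any external
image data.

It is aimed at quantitative cell biologists and image analysts who want a
scriptable, deterministic equivalent of the usual Fiji/QuPath point-and-click
chain (3D objects counter, Delaunay cluster features, line scans), with the
statistics layer attached.

## What it computes

**Segmentation** (`segment_nuclei`): Gaussian smoothing specified in μm
(isotropic in physical space even for anisotropic stacks), global Otsu or
manual thresholding, 3D/2D connected-component labelling (face or full
connectivity), then object filtering: components with fewer than
`min_size = 50` voxels are dropped (inclusive rule), border-touching
components are dropped as partial nuclei, and an optional solidity rule
rejects aggregates.

**Morphometry** (`measure_nuclei`): per nucleus,

- volume `V = voxel count × dx·dy·dz` (exact), or cross-sectional area
  `CSA = pixel count × dx·dy` on planes;
- surface area by exposed-face counting (deterministic, exact for voxel
  solids) or by a coarea estimator `∫ |∇(G_σ ∗ χ)| dV` (accurate for smooth
  shapes);
- equivalent diameter `(6V/π)^{1/3}` (3D) or `(4·CSA/π)^{1/2}` (2D),
  centroids, mean channel intensities;
- cytoplasm by subtraction, `V_cyto = V_total − V_nuclear`.

**Spatial statistics** (`tile_rois`, `delaunay_graph`, `crowding_indices`):
random non-overlapping ROI boxes (default eight 1,500 × 1,500 μm boxes, with
an optional exclusion mask), Delaunay triangulation of nucleus centroids with
internuclear edge lengths, and the size-corrected crowding index

```
crowding_index_i = mean incident Delaunay edge length_i / equivalent diameter_i
```

which is exactly invariant under joint spatial scaling — crowding free of
nuclear-size confounding.

**Line scans** (`long_axis`, `sample_profile`, `peripheral_fraction`): a
measurement line through the long axis of each nucleus on the middle z-plane,
and the peripheral-enrichment fraction

```
PF = ∫_{margin} I ds / ∫_{nucleus span} I ds ,   margin = 3 μm from each edge
```

**Densitometry and decay** (`lane_auc`, `summarize_decay`): background-
subtracted lane AUC normalised to a loading control; cycloheximide-chase
courses (0/6/12 h) summarised per timepoint with condition-wise t tests and
an optional log-linear half-life fit.

**Group statistics** (`compare_two`, `compare_many`, `dunn_test`): a
normality-gated policy — Shapiro-Wilk per group on raw and log scale; if all
groups pass on a common scale, t test / one-way ANOVA + Tukey HSD, otherwise
Mann-Whitney U (exact for small tie-free samples) / Kruskal-Wallis + Dunn's
test with tie-corrected variance and Holm adjustment. Every result records
the branch taken and the normality p-values behind it.

**Synthetic data** (`make_nucleus_field`, `make_plane_field`,
`make_membrane_channel`, `make_decay_course`): fields of ellipsoidal nuclei
with exact per-nucleus ground truth (volume `4/3·π·abc`, Knud-Thomsen surface
area), two-population median shifts, controllable crowding, a membrane
channel with a calibrated rim-enrichment parameter, and noisy exponential
decay courses. Identical spec + seed gives bit-identical output.

## Worked example

Simulate a control line and a KRAS-on line whose nuclei are scaled by 0.85 in
every linear dimension (volume ratio 0.85³ ≈ 0.614), then run the full
volume pipeline:

```r
library(nucmorph)

ctrl <- field_spec(60, extent = c(180, 180, 16), voxel_size = c(0.4, 0.4, 0.4),
                   radii = c(5.5, 4.5, 3), radii_gsd = 1.1, noise_sd = 5, seed = 1)
kras <- ctrl
kras$radii <- ctrl$radii * 0.85

cfg <- run_config(conditions = list(ctrl = ctrl, kras = kras),
                  segmentation = list(smooth_sigma = 0.8), seed = 11)
res <- run_volume_pipeline(cfg)
res
```

```
<results_bundle>
  nuclei: 120 rows
  ctrl: 60 objects after filtering (removed: 0 small, 0 border, 0 aggregated); threshold otsu = 77
  kras: 60 objects after filtering (removed: 0 small, 0 border, 0 aggregated); threshold otsu = 73
Welch two-sided t test: statistic = 11.17, p = 9.873e-20 [parametric branch]
  ctrl: n = 60, mean = 333.5 +/- 7.65 SEM
  kras: n = 60, mean = 227.5 +/- 5.6 SEM
```

All 60 nuclei per condition are recovered, the automatic threshold and the
filter counts are logged, and the size difference is detected (here the gate
chose the parametric branch because both simulated volume distributions pass
normality). The recovered median-volume ratio,

```r
med <- tapply(res$tables$nuclei$volume_um3, res$tables$nuclei$condition, median)
round(med[["kras"]] / med[["ctrl"]], 3)
#> [1] 0.676
```

sits close to the ground-truth 0.614; the residual gap is the segmentation
dilation bias discussed in the methods vignette (it shrinks with voxel size
and sample size).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/nucmorph` (`nucmorph simulate|segment|crowding|compare`).

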
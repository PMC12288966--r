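---
title: "nucmorph: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucmorph: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each estimator, and the choices made where the underlying
imaging protocols leave the method open. The companion README shows the
user-facing workflow; here the emphasis is on *why* each stage is built the
way it is.

## The analysis chain

The package quantifies nuclear morphology in two imaging regimes and ties
them to a statistics layer:

1. **3D fluorescence stacks** (DAPI-like nuclear stain, optionally a
   whole-cell and a membrane-protein channel): smooth → threshold → label →
   filter → per-nucleus volume, surface area, centroid, intensity; cytoplasm
   as total-minus-nuclear volume; line scans for peripheral enrichment of a
   membrane channel.
2. **2D histology planes** (H&E/Feulgen "optical density" images): random
   ROI tiling over the tissue, per-ROI nucleus detection, cross-sectional
   area, and Delaunay-based crowding.
3. **Group comparisons**: normality-gated parametric/nonparametric tests
   with the matching post hoc procedures, reporting median ± IQR or
   mean ± SEM as appropriate.

All coordinates are physical micrometres internally. Arrays are indexed
`[x, y, z]` (the natural column-major layout in R; a plane is `[x, y]`), the
voxel with index `i` spans `[(i-1)·h, i·h)` along an axis with spacing `h`,
and its centre sits at `(i-0.5)·h`. ROI boxes are half-open
`[x0, x0+box) × [y0, y0+box)`. These conventions are used everywhere and are
stated only here.

## Segmentation

*Smoothing.* `smooth_grid(grid, sigma)` takes `sigma` in μm and converts it
to voxels per axis, so anisotropic stacks are smoothed isotropically in
physical space. Boundaries are reflective (a constant image stays constant);
`sigma = 0` is the identity. The default pipeline sigma (0.5–0.8 μm) is a
fraction of a nuclear radius: enough to suppress staining heterogeneity,
small enough not to merge neighbours.

*Thresholding.* The reference workflow thresholded manually per image, which
is not reproducible; `threshold_grid` therefore offers Otsu's
between-class-variance criterion on the global integer histogram as the
automatic stand-in, and retains a manual mode for parity. The threshold is
inclusive (`intensity ≥ value`) and is always recorded in the label map's
provenance. An empty or all-foreground mask warns rather than errors, since
either can be a legitimate (if useless) outcome of a manual value.

*Labelling.* Connected components under face connectivity by default
(6-neighbourhood in 3D, 4 in 2D); full (edge+vertex) connectivity is
available. Face connectivity is the conservative choice when nuclei can
approach each other: it refuses to bridge voxels that touch only diagonally.
The implementation is a compiled flood fill; the test suite holds it to
exact agreement with an independent brute-force flood fill on random masks.

*Filtering.* Three rules, each logged with its removal count:

- **size**: components with fewer than `min_size` voxels are removed. The
  cutoff is *inclusive* (a 50-voxel object survives `min_size = 50`); the
  protocol this mirrors states only a "minimum filter size of 50", and the
  inclusive reading is the one under which the stated size is itself valid.
- **border**: components touching any lattice boundary are removed when
  `exclude_border` (the default) — this operationalises "partial nuclei".
- **solidity** (off by default): components whose voxel count falls below
  `1 − max_solidity_deficit` of their convex-hull voxel count are removed —
  an automated stand-in for the manual exclusion of aggregated nuclei. The
  hull is the exact pixel hull in 2D and a slice-wise hull in 3D (no 3D hull
  dependency is used); since fused nuclei are concave mostly in-plane, the
  slice-wise deficit captures them.

Filtering is idempotent and monotone in `min_size`, and both properties are
tested.

## Morphometry

Volume and CSA are exact voxel/pixel tallies times the voxel/pixel measure —
no interpolation, so they scale exactly as `s³`/`s²` under voxel-size
rescaling.

Surface area is the one measure where the estimator genuinely matters, and
the reference protocol does not state its method. Two estimators are
provided, and the choice is recorded in the output:

- `voxel_faces` (default): count exposed voxel faces with per-orientation
  areas (`dy·dz`, `dx·dz`, `dx·dy`). Deterministic, parameter-free, exact
  for voxel-aligned solids (a cube of `n³` voxels measures exactly
  `6n²v²`) — but it overestimates smooth surfaces by a staircase factor
  approaching 1.5 for spheres. It is kept as the default because it is an
  exact, auditable property of the label map itself.
- `coarea`: smooth the component's indicator function with a small Gaussian
  (`sigma_vox = 1.5` voxels by default) and integrate the gradient
  magnitude, `A ≈ Σ |∇(G_σ ∗ χ)| dV` — the coarea formula. For a 5 μm
  sphere at 0.2 μm voxels this is accurate to well under 1%; the smoothing
  scale trades voxelisation bias (too small) against curvature bias
  (too large, biased like `σ²/r²`). This estimator is the one held to the
  package's accuracy contracts. An iso-surface triangulation would serve the
  same purpose; the coarea integral was chosen because it needs no mesh
  machinery, handles anisotropic voxels naturally, and its single parameter
  has a transparent geometric meaning.

The **equivalent diameter** — `(6V/π)^{1/3}` in 3D, `(4·CSA/π)^{1/2}` in
2D — is the "nuclear diameter" used by the crowding index. The underlying
protocol does not say which diameter it divided by; the equivalent diameter
was chosen over a Feret diameter because it is rotation-invariant, exactly
derivable from the measured size, and monotone in it. The choice is
documented in the output and the records column is explicit
(`equivalent_diameter_um`), so a Feret-based variant can be substituted by
supplying a different column.

Cytoplasm-by-subtraction clamps small negative results (segmentation noise)
to zero with a warning, and treats nuclear volume above 1.5× the total as a
gross inconsistency (error): past that point the two channels cannot be
describing the same cell.

## Crowding

"Internuclear distance" is the centroid-to-centroid Delaunay edge length
(the convention of the point-pattern tooling this mirrors), not a
boundary-to-boundary distance. Each nucleus is summarised by the **mean** of
its incident edge lengths by default — the protocol is silent on mean versus
median, so both are available (`summary = "median"`). Hull-boundary nuclei
carry biased long edges; no edge pruning is applied by default, matching the
protocol's silence, and nuclei without neighbours are flagged and excluded
from summaries rather than silently dropped.

The crowding index divides by the equivalent diameter, which makes it
exactly invariant under joint scaling of positions and sizes — that
invariance, not any absolute calibration, is what justifies using it to
compare crowding across conditions with different nuclear sizes, and it is
asserted to machine precision in the tests.

Degenerate inputs: fewer than two centroids give an empty graph; exactly
collinear centroids cannot be triangulated and fall back to a
nearest-neighbour chain, flagged `degenerate` in the result.

ROI tiling samples axis-aligned boxes uniformly by rejection: in bounds,
non-overlapping, and fully outside the exclusion mask when one is given.
"Preferential avoidance" of stroma/islet regions is implemented as a *hard*
mask — stricter than the manual protocol, but reproducible. If
non-overlapping placement fails within the attempt budget the constraint is
relaxed with a warning; if the mask leaves no room at all, that is an error.

## Line scans and the membrane generator

The measurement: a segment through the nucleus's long axis (principal axis
of the mask's pixel coordinates, extended 2 μm past the mask at each end so
the edges are sampled), intensities bilinearly interpolated on the middle
z-plane at 0.1 μm steps, and the peripheral fraction

> PF = (signal within 3 μm of either nuclear edge) / (signal across the
> nuclear span),

with trapezoidal integration and interpolated partial end intervals. Two
documented readings of "total signal across the line" exist; the denominator
defaults to the trans-nuclear span (consistent with the numerator's
anchoring at the nuclear edges) and can be switched to the full sampled
segment. Nuclei whose span is ≤ 2×margin make the fraction trivially 1 and
are flagged. At aspect ratio 1 the principal axis is undefined; the tie
breaks to the image x-axis. The 0.1 μm step and bilinear interpolation are
package choices (the interactive tooling this mirrors states neither); the
uniform-profile closed form PF = 2d/L is recovered to within one sampling
step, which bounds the discretisation error.

The synthetic membrane channel needs care, because a 1D line integral does
not weight a 3D shell the way voxel sums do. `membrane_spec(rim_fraction =
ρ)` places signal in a rim shell within `rim_width` of the nuclear surface
(Euclidean distance computed on the rendered voxel mask — the same geometry
the measurement sees), remainder uniform in the interior, under one of two
calibrations:

- `"volume"` (default): ρ is the volumetric share — voxel sums over the rim
  shell recover ρ essentially exactly. This is the natural ground truth for
  intensity-based readouts.
- `"linescan"`: the rim intensity is solved per nucleus so that the
  *expected long-axis line-scan fraction at the chosen margin* equals ρ.
  This is the right ground truth when ρ is meant to be the percentage a
  line-scan assay reports (e.g. simulating conditions at 72% vs 52%),
  because for a sphere of radius r the volumetric and line-scan readings of
  the same shell differ grossly: the line crosses a `w`-thick rim over a
  fraction `w/r` of its half-length, while the shell holds
  `1 − (1 − w/r)³` of the volume.

The linescan calibration has a feasibility window set by geometry: with
margin `d`, rim width `w` and in-plane long axis `L`, the attainable
fraction is bounded below by roughly `2(d−w)/(L−2w)` (the margin inevitably
collects interior signal) and above by the rim's own share of the line.
Requests outside the window raise an informative error rather than silently
mis-calibrating. The default line-scan study geometry — spheres of median
radius ≈ 6 μm — keeps fractions from ~0.15 upward attainable at the 3 μm
margin; these sizes are typical of cultured tumour-line nuclei.

## Densitometry and decay

Lane AUC is the trapezoidal area above a background baseline (`zero`, `min`,
or a `linear` first-to-last baseline), clipped at zero, and is exactly
linear in the profile under zero background. Normalisation requires a
strictly positive control-lane AUC.

Chase courses are summarised per timepoint (mean, SEM, n) after normalising
each replicate to its own t = 0 level, with per-timepoint two-sided t tests
between two conditions — mirroring how such assays are usually reported. A
log-linear least-squares fit additionally yields `t½ = ln 2 / k̂`; the
half-life is labelled in the output as an extension beyond the per-timepoint
comparison, since the underlying assay design only compares timepoints.
Nonpositive levels abort before the log fit.

## The statistics layer

The gate: Shapiro-Wilk per group at α = 0.05 on the raw and the log scale
("normality and lognormality"); if **all** groups pass on at least one
common scale, the parametric branch is taken (Welch t test, or one-way ANOVA
with Tukey HSD), otherwise the nonparametric branch (two-sided Mann-Whitney
U, or Kruskal-Wallis with Dunn's post hoc). Groups smaller than 3 cannot be
gated and force the nonparametric branch with a warning. Groups larger than
5,000 are deterministically subsampled for the gate (Shapiro-Wilk's range);
with such n the gate is close to a formality anyway. Every result records
the branch, the gate p-values, and the summaries appropriate to the branch.

Mann-Whitney p-values are exact (full U distribution) when `min(n) ≤ 8` and
the data are tie-free; ties fall back to the tie-corrected normal
approximation with a warning. Dunn's z statistics use the tie-corrected rank
variance `N(N+1)/12 − Σ(t³−t)/(12(N−1))`. The post hoc multiplicity family
is not specified by the protocol this mirrors; the default is Holm over all
pairs (uniformly more powerful than Bonferroni at the same error control),
with Bonferroni and unadjusted available, and the adjustment is always named
in the output table.

## What the generator emulates — and what it does not

The synthetic fields emulate: ellipsoidal nuclei with lognormal size
variation, two-population median shifts applied as an exact scale factor
(population 2 reuses population 1's draws scaled by `median_scale`, so the
ground-truth median-volume ratio is exactly `median_scale³` for even counts
— a variance-matched paired design that makes recovery tests sharp),
Poisson-disc-style spacing, additive Gaussian noise on a constant background
clipped to the bit depth, hexagonal-lattice layouts for spatial oracles, and
rim-enriched membrane channels. Nuclei are axis-aligned ellipsoids by
default (optional in-plane rotation) precisely so the analytic volume and
Knud-Thomsen surface oracles stay exact.

Deliberately *not* modelled: chromatin texture, out-of-focus/PSF blur,
photorealistic H&E colour, stain stoichiometry, nuclear shape irregularity,
and spatial noise correlation. Passing the recovery tests therefore
demonstrates that the measurement chain is unbiased and correctly calibrated
on geometrically clean data; it does not certify segmentation quality on
textured, blurred real tissue, where thresholding and aggregate handling
dominate the error budget. The acquisition protocols this package mirrors do
not characterise their imaging noise, PSF, or staining variance; the
generator's defaults (8-bit depth, background 10, noise SD 5, foreground
180) are stated choices, not inferences.

A known, visible bias on clean data: thresholding after smoothing dilates
objects by a fraction of a voxel, so measured volumes run a few percent
above truth, and the bias is relatively larger for smaller nuclei — which
nudges recovered volume *ratios* toward 1 (e.g. ≈ 0.64–0.66 recovered for a
ground-truth 0.614 at 0.4 μm voxels). It shrinks with voxel size; it is the
reason the end-to-end contracts are set at 10% while the direct geometry
contracts sit at 3–5%.

## Determinism and problem sizes

Every stochastic stage takes an explicit integer seed, and pipelines derive
per-condition seeds from the master seed (`seed + 7919·index`), so a
`run_config` plus seed fixes every output byte; `bundle_hash` exists to make
that an assertable property. Identical spec + seed renders bit-identical
images.

The test suite and the acceptance script run at sizes chosen to exercise the
contracts while staying desk-sized: single-nucleus geometry checks at
0.2–0.25 μm voxels; 50 random 10×10×5 masks and 20 random ≤30-point sets
against the exact oracles; 20 six-nucleus fields for count recovery; 200
nuclei per condition for the volume-shift recovery and 50 per condition for
the enrichment recovery; 1,000 null simulations at n = 50/group for type-I
calibration. These are the package's own choices of problem size; the
recovered-quantity tolerances (3% volume, 5% coarea surface area, 0.05 on
peripheral fractions, 10% on the end-to-end median-volume ratio) are stated
in, and enforced by, `tests/testthat/test-acceptance.R`.

## Known limitations

- No watershed or other splitting of touching nuclei: the generator's
  spacing constraint avoids merges, and real aggregates are only *excluded*
  (border/solidity rules), as in the manual protocol.
- The solidity rule in 3D uses slice-wise hulls, which under-detects
  aggregates fused purely along z.
- Whole-slide pyramidal formats, stain deconvolution, GUIs, survival and
  sequencing analyses are out of scope.
- The Shapiro-Wilk gate at huge n flags trivial departures from normality;
  that matches the mirrored protocol, but users comparing 10⁵ nuclei should
  expect (and want) the nonparametric branch essentially always.
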
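---
title: "Models and methods behind thyromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thyromorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyromorph)
```

`thyromorph` quantifies thyroid follicle architecture from three-channel
fluorescence micrographs. This vignette records the models the package
implements, the parameters that matter, the numerical choices that were
genuinely open, and what the synthetic phantoms do and do not validate.

## The tissue model

A thyroid follicle in an equatorial (mid-)section is modelled as three
nested compartments: a roughly circular *lumen* (extracellular, stores
thyroglobulin), an *epithelial annulus* of thyrocytes around it, and a thin
*basal lamina* at the epithelium's outer edge. Nuclei sit in the epithelium;
nuclei detected inside a lumen are counted as shed, terminally
differentiated thyrocytes ("dead-cell remnants"). Three stains map onto
three raster channels: marker (basal lamina or cathepsins; green role),
cytoplasm (red role) and nuclei (blue role). All geometry is measured in
µm via a single `pixel_size` (µm/px); areas convert by `pixel_size²`.

## Segmentation pipeline

1. **All-tissue mask.** The unweighted mean of the three channels is
   thresholded (the merge weights of the original acquisition software are
   not standardized, so an unweighted mean is used). Thresholds are manual,
   batch-level configuration values: one value per channel per batch,
   applied to every image of the batch. Comparison is inclusive (`>=`) so
   saturated pixels are kept. An Otsu fallback exists but is off by
   default.
2. **Boundary skeleton.** The thresholded marker channel is closed (3 × 3)
   to bridge single-pixel staining gaps, then reduced to a one-pixel
   skeleton by Zhang–Suen thinning. Thinning runs to convergence, so it is
   idempotent, and a gap-free ring stays one closed curve.
3. **Lumen primary objects.** Connected components (8-connectivity) of the
   *inverted* all-tissue mask, keeping components whose equivalent diameter
   `2·sqrt(area/π)` lies in 25–800 px. Objects touching the image border
   are discarded (partial objects are unmeasurable, and the background
   component always touches the border). Interior holes — e.g. a dead-cell
   remnant inside a lumen — are filled after the size filter.
4. **Roundness filter.** Objects with form factor `4π·area/perimeter²`
   below 0.3 are removed (inclusive boundary: exactly 0.3 is retained; the
   strictness is a package choice, as is documented below for the perimeter
   estimator).
5. **Follicles by bounded propagation.** Each lumen grows outward through
   passable pixels of the boundary image (all-tissue minus skeleton),
   stopping at barrier pixels, the image edge, or a geodesic distance of
   30 px from the lumen boundary. Distances are chamfer-weighted (1
   orthogonal, √2 diagonal), so the cap is approximately Euclidean: exact
   along the axes, ~4% short on diagonals. Diagonal steps cannot slip
   between two diagonally adjacent barrier pixels, so a closed skeleton
   curve genuinely contains the growth. Contested pixels go to the nearer
   seed, ties to the lower label (both rules are package choices; only the
   30 px cap is inherited from the protocol the pipeline reproduces). After
   propagation, skeleton pixels adjacent to a grown follicle are absorbed
   into it (2 passes, matching a 1–2 px lamina), because the basal lamina
   belongs to its follicle; without absorption every follicle would be
   systematically one lamina-width too small.
6. **Epithelium and relations.** Epithelium k = follicle k − lumen k.
   Nuclei are identified from the nuclei channel with a
   distance-transform-watershed declumping step and assigned to the
   follicle containing their centroid (centroid assignment rather than
   overlap-fraction assignment is a package choice; the two differ only for
   nuclei straddling a boundary). Nuclei whose centroid falls inside a
   lumen are the dead-cell remnants of that lumen.

Interactive object editing is replaced by a reproducible override file
(CSV of label ids to drop): reproducibility over interactivity.

## Morphometric definitions

- `EExt = sqrt(A_follicle/π) − sqrt(A_lumen/π)` (µm). The equivalent-disc
  radius difference equals the epithelial height exactly for concentric
  circular follicles and degrades gracefully for elliptical ones. The
  protocol literature defers the epithelial-extension equation to earlier
  work without printing it; this definition is the package's own and is
  flagged prominently here for anyone comparing absolute values.
- `thyrocyte_area = A_epithelium / n_cells` (µm² per cell), missing when a
  follicle has no assigned nuclei.
- Section means are unweighted over follicles; cell density is
  `1000 · Σ n_cells / Σ A_follicle` (cells per 1000 µm²) and is invariant
  to splitting a section into sub-images; the dead-cell percentage
  normalizes intraluminal remnants to the section's total nucleus count.
- The lumen-area heat map maps areas linearly onto a viridis ramp clipped
  at a configured `vmax_area` (µm²). A fixed numeric ceiling replaces the
  practice of pasting a reference follicle of cut-off size into each image:
  both standardize the color scale across sections, but the explicit
  ceiling is bit-reproducible.

## The perimeter estimator (and why it is documented)

The form factor depends entirely on the perimeter estimator, so the
estimator is fixed and documented. For convex objects (solidity ≥ 0.95
against the convex-hull interior) the perimeter is the convex-hull
perimeter of the object's pixel squares minus `4 − π`: the squares-hull
measures the object dilated by a half-pixel square, which adds exactly 4 to
a convex perimeter, whereas the smooth envelope the form factor refers to
adds π. For non-convex objects the 4-direction Crofton estimate is used,
floored by the corrected hull. The isoperimetric bound `2·sqrt(π·area)` is
always applied, so form factors never exceed 1. Calibration on analytic
shapes: a rasterized disc of radius 64 px yields FF = 0.987 (analytic 1.0);
a 20 × 20 square yields 0.803 (analytic π/4 ≈ 0.785); a 1 × 10 bar yields
0.281 (analytic ≈ 0.260) — all within the ±0.05 rasterization tolerance the
package promises, which deliberately absorbs the estimator choice.

## Intensity compartmentalization

Total marker signal is the plain intensity sum; the intracellular part is
the sum under the thresholded cytoplasm mask; the extracellular part
(luminal plus apical-pericellular, which mask logic cannot separate) is
obtained by subtraction, so conservation
`intracellular + extracellular = total` holds exactly by construction.
Per-cell normalization divides by the nucleus count of the whole field; a
per-follicle normalization column is available but is an extension beyond
the field-level protocol. No background subtraction or bleed-through
correction is applied.

## Cohort statistics

Measurements from different animal cohorts are made comparable as fold
changes over the wild-type mean *of the same cohort and metric*, so the WT
mean maps to 1.0 in every cohort by construction. Genotypes are compared
against the control by one-way ANOVA with Dunnett's many-to-one adjustment
(via `multcomp`), at α = 0.05, on the fold-change scale; means ± SD are
reported on that scale too. The analysis unit defaults to animal means
(each animal one observation) with an `unit = "observation"` switch,
because the protocol does not state whether animal- or follicle-level
values entered the ANOVA and animal means are the conservative choice.
Densitometry support is limited to the ratio arithmetic
(`band / lane_total`); gel image processing is out of scope.

## The phantom generator

`phantom_spec()` describes a synthetic section with exact ground truth; its
defaults are the package's standard validation conditions:

| parameter | default | rationale |
|---|---|---|
| `image_size` | 2048 × 2048 px | a stitched mid-section at typical confocal resolution |
| `pixel_size` | 0.62 µm/px | a common 10×/1024-px confocal sampling; no standard value exists, so it is a free, exposed choice |
| `n_follicles` | 30 | a mid-section's worth of complete follicles |
| `lumen_radius_range` | 30–70 px (19–43 µm) | small-to-medium rodent follicles |
| `epithelium_thickness_range` | 14–20 px (~9–12 µm) | cuboidal epithelium |
| `nuclei_per_follicle_range` | 8–24 | one nuclear ring per annulus cross-section |
| `dead_cell_fraction` | 0.04 | a few percent of nuclei shed into lumina |
| `luminal_marker_fraction` | 0.31 | the extracellular share of marker signal in control tissue |
| `puncta_per_cell` | 3 | vesicular marker granules per thyrocyte |
| `noise_sd` | 0.01 | mild background noise on the [0, 1] scale |

Follicle centers are placed by rejection sampling with a 5 px minimum gap
between outer boundaries (follicles in mid-sections are discrete and
non-touching); failure after the retry limit raises an error naming the
follicle. Per-follicle nucleus counts are drawn from the range;
`round(dead_cell_fraction × total)` of all nuclei are reassigned to
intraluminal positions, so the section-level dead-cell fraction equals the
parameter up to rounding. Epithelial nuclei are placed on a jittered ring
at mid-annulus radius with ≥ 9 px center spacing (so declumping can always
separate them); nuclei are rendered as 7 px discs softened by a σ = 1
Gaussian blur — blob-like objects without chromatin texture. The marker
channel renders the basal lamina as the outermost ~1.5 px of each annulus,
plus crisp vesicular puncta; diffuse luminal signal is added so the luminal
share of total marker signal equals `luminal_marker_fraction` exactly.
Noise is additive Gaussian, clipped to [0, 1]; truth marker sums are
recorded from the noise-free rendering, so with noise the image integral
exceeds the truth total by the background noise. Identical specs (including
the seed) produce bit-identical phantoms. `luminal_marker_fraction = 1` is
rejected, since the rendered basal lamina always contributes intracellular
signal.

**What phantom tests show — and what they do not.** Phantoms share the
statistical and geometric structure the pipeline assumes: closed round
lumina, annular epithelia, a thin continuous basal lamina, well-separated
blob nuclei, stationary Gaussian noise. They do not model optical
point-spread, uneven illumination, autofluorescence, touching or collapsed
follicles, interrupted lamina staining, or 3-D sectioning artifacts.
Passing phantom recovery therefore validates the pipeline's logic and
numerics, not its robustness to degraded real-world staining — thresholds
for real batches must still be set per batch.

## Numerical choices and degenerate inputs

- Problem sizes: validation runs use a 2048² phantom with 30 follicles for
  end-to-end recovery and 256–512 px fixtures elsewhere; the Monte-Carlo
  null check of the Dunnett layer uses 1000 replicates of 4 groups × 8
  animals.
- Empty inputs are values, not errors: an empty foreground yields an empty
  label map; an empty record list yields an `n_follicles = 0` summary with
  missing means; a zero marker channel yields zero signals with
  undefined-flagged percentages; `n_cells = 0` flags per-cell fields
  missing while percentages are still returned.
- Label maps are relabelled to contiguous `1..K` after every filter,
  preserving the original order.
- Equidistant propagation ties go to the lower label; the roundness and
  threshold comparisons are inclusive.
- 16-bit TIFF is the raster interchange format (labels stored as
  `label/65535`), CSV for tables, YAML for configuration.

## Known limitations

- `EExt` is exact only for concentric circular follicles; strongly
  elliptical or folded follicles bias it low relative to true epithelial
  height.
- The fixed 30 px expansion cap and the 25–800 px lumen diameter range are
  resolution-dependent; both must be rescaled when the magnification
  changes.
- Centroid-based nucleus assignment can misattribute a nucleus that
  straddles a follicle boundary.
- The form-factor estimator's ±0.05 tolerance is a rasterization tolerance
  for objects ≳ 16 px radius; much smaller objects carry larger relative
  perimeter error.
- Cohort comparison assumes approximately normal fold changes within
  genotype; no hierarchical (animal-within-cohort) modelling is offered.
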
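---
title: "Segmentation-driven morphological profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-driven morphological profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpaintr)
```

## The problem

Cell Painting assays stain five cellular compartments with fluorescent dyes
(Hoechst for DNA, concanavalin A for the ER, SYTO 14 for nucleoli and
cytoplasmic RNA, phalloidin/WGA for actin-Golgi-plasma membrane, MitoTracker
for mitochondria) and image them alongside brightfield planes, typically on
384-well plates (16 rows A-P, 24 columns) with several fields of view per
well. Morphological profiling turns each segmented cell into a vector of
quantitative descriptors and compares perturbations in that feature space.
Segmentation quality is the dominant error source: a merged or fragmented
cell contaminates every feature measured on it.

`cellpaintr` covers the workflow from outline annotations to prioritized
feature tables. This vignette records the models each stage implements, the
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinate and data conventions

Images and masks are numeric matrices indexed `[row, col]` with row 1 at the
top; reported pixel coordinates are 0-based `(row, col)` (in feature columns,
`X` = column, `Y` = row). Label masks use 0 for background and positive
integers for instances. Plate coordinates follow the fused
`"PLATE-RowCol-Site"` convention (e.g. `BR00116991-A02-5`) with a zero-padded
two-digit column; parsing also accepts one digit. The default site is 5, the
center of a 3 × 3 field grid — center fields avoid border artifacts.

## Ground-truth mask preparation

Outline annotations mark instance borders with value 255 on black. Masks are
recovered in four steps: invert, label connected components, remove
background and debris, and dilate to restore the border pixels.

*Connectivity.* Interiors are labeled with 4-connectivity: outline strokes
drawn with 8-connected pens seal 4-connected interiors, so diagonal leakage
through a 1-px stroke is impossible.

*Background and debris removal.* The upstream datasets define redundant
objects via their own segmentation outputs, which are not available in
general. We instead remove every region touching the image border (the
background, plus objects cut by the frame) and any region below `min_area`
(default 15 px). When a reference object count is supplied, the result is
cross-checked against it with a warning.

*Border restoration.* Each instance is dilated by a square structuring
element of side `2r + 1` with `r = max(1, round(0.5 + sqrt(A)/50))`, `A` the
mean object area. The formula is a concrete stand-in for an area-tuned
kernel: for typical cell areas (500-3000 px) it yields r = 1, growing slowly
for very large objects; it is exposed as `radius` for direct override.
Contested pixels go to the instance whose nearest original pixel is closest
(Euclidean), ties to the lower label — deterministic and independent of
processing order. Dilation can neither merge instances (each keeps its
original pixels, which are strictly closer to it) nor shrink any instance.

The centered ROI crop (default 960 px from 1080-px fields upstream;
`floor((dim - size)/2)` offset per axis) truncates, rather than removes,
objects extending beyond the window.

## Instance segmentation from confidence maps

The segmentation engine consumes per-class *class* and *border* confidence
maps in [0, 1]. Maps can be read from float TIFFs produced by any external
model; the package also ships a classical generator so the pipeline runs
without a trained network: the DNA channel scores nuclei and
`max(RNA, DNA)` scores cells, each smoothed (Gaussian sigma 2 px), rescaled,
and passed through a soft threshold centred on the Otsu level; border maps
are max-normalized Sobel gradient magnitudes of the class maps. This
generator is a baseline in its own right, not an emulation of any particular
model: on well-separated synthetic scenes it localizes nuclei and boundaries
correctly, while crowded real scenes are exactly where a learned model earns
its keep.

Instances are recovered by marker-based flooding: foreground is
`class >= class_threshold` (default 0.5, the natural probability midpoint);
seeds are 4-connected components where `class - border >= seed_margin`
(default 0.3, requiring clear interior evidence); the border map is flooded
from the seeds within the foreground (seeded region growing in the
CellProfiler style, EBImage's `propagate`, with a small spatial
regularization lambda = 1e-4 to break flat-relief ties by distance). Each
seed yields one instance; foreground components no seed can reach become
instances of their own, so the output always partitions the thresholded
foreground. For cell segmentation a `semantic` mode labels the foreground by
connected components only, deferring instance separation entirely to
nucleus-guided refinement — useful when the cell-class model is reliable
semantically but poor at instance boundaries.

## Nucleus-guided refinement

Two procedures align cell instances with nuclei, assuming predominantly
mononuclear cells.

*Splitting.* A nucleus belongs to the cell containing its rounded centroid
pixel (round half up, clipped to the image). Cells owning ≥ 2 centroids are
partitioned by assigning each pixel to the nearest owned centroid (Euclidean,
ties to the lower nucleus label); parts get fresh labels above the current
maximum. Nearest-centroid parts can be geometrically disconnected for concave
cells; they are kept as one label — re-splitting would second-guess the
stated assignment rule. The operation is idempotent: after one pass no cell
owns two centroids.

*Merging/removal.* Anucleate cells below `min_area` are artifacts. The
default `min_area` is 0.4 × the median area of nucleated cells in the same
image (fallback 100 px when none exists) — relative to the image's own cell
population rather than absolute, since magnification and cell line vary.
Fragments with no 8-connected neighboring cell are deleted as noise ("poorly
connected" is interpreted as exactly this adjacency test). Otherwise the
fragment merges into the neighbor minimizing mean border confidence along
the shared interface (fragment-side pixels adjacent to that neighbor): low
border evidence between two regions is evidence they are one object. Ties go
to the longest interface, then the lower label. Fragments are processed in
ascending label order against the evolving mask; idempotence at fixed
`min_area` is property-tested. Note that the area-relative default recomputes
on the refined mask if applied twice, so exact idempotence is guaranteed for
explicit `min_area`.

The cytoplasm of cell *k* is its pixels minus its owned nucleus, so
`area(cell) = area(nucleus ∩ cell) + area(cytoplasm)` per object.

## The feature catalog

Features follow published CellProfiler conventions where applicable; every
ambiguity is fixed and listed here. Per configuration the catalog column
count is closed-form: AreaShape 25 + Zernike (30 at degree 9); Intensity
15 per channel; Location 2 + 4 per channel; Correlation 8 per unordered
channel pair; Granularity `n_scales` per channel; RadialDistribution
`3 n_bins` per channel; Neighbors 5; Texture 13 per channel per offset.
Defaults: Zernike degree 9, 16 granularity scales, 4 radial bins, 8 texture
levels at offset 3 averaged over 4 directions, neighbor distance 5 px. The
catalog is configuration-driven rather than locked to any particular
published total, which is not decomposable from group names alone.

Numerical choices worth knowing:

- **Perimeter** is the Moore-traced outer boundary path length (axial step 1,
  diagonal sqrt(2)); single pixels contribute 1. Second-moment shape measures
  carry the standard 1/12 per-pixel variance correction.
- **Zernike magnitudes** map the object to the unit disk via centroid and
  minimum enclosing radius and use uniform pixel weights `1/N`; magnitudes
  are rotation-invariant and checked against direct numerical integration.
- **Quantiles** use linear interpolation (R type 7); Std and MAD are
  population-style; edge pixels are object pixels with a non-object
  4-neighbor.
- **Correlation** reports Pearson (0 under zero variance), the regression
  slope in both directions (b on a, and a on b), overlap, Manders M1/M2 with
  per-channel Otsu thresholds inside the object, and K1/K2. All zero-denominator
  ratios are 0.
- **Granularity** is the incremental spectrum: element *i* is 100 × the mean
  intensity removed between disk openings of radius *i* − 1 and *i*, over the
  original mean. Openings run on the local crop with surrounding context in
  place, so a globally constant image yields an all-zero spectrum.
- **Radial distribution** bins pixels by `d_centroid/(d_centroid + d_edge)`
  (exact fractional radius on a disk); RadialCV uses 8 angular wedges.
- **Haralick** quantizes per-object min-max to `levels` gray levels
  (constant objects map to level 0), accumulates symmetric normalized
  co-occurrence matrices over within-object pairs, averages the 13 statistics
  over directions with at least one pair, and defines zero-variance
  statistics as 0. Logarithms are base 2; levels are indexed from 0.
- **Degenerate objects** (an anucleate cell's nucleus row, an empty
  cytoplasm) produce all-zero feature rows, never missing values, keeping
  row counts at objects × compartments.

## Evaluation, QC and prioritization

Matching is greedy one-to-one in descending IoU with `IoU >= threshold`
(inclusive; default 0.5). At thresholds ≥ 0.5 on internally disjoint masks a
prediction can exceed the threshold with at most one ground-truth object, so
greedy equals optimal matching — verified against exhaustive bipartite
matching in the suite. AP is the detection-Jaccard form `TP/(TP+FP+FN)`, not
ranked-precision AP; consequently `AP <= min(P, R) <= F1`. Both the mean
matched-pair IoU and the pixelwise foreground IoU are reported, since
summary "IoU" figures in the literature can mean either.

Feature QC min-max normalizes each feature using the reference column's
bounds (a `pooled` option makes the comparison symmetric); zero-range
features contribute 0 where equal and 1 where not. MSE and MAE are pooled
over objects × features per group. Prioritization scans features by
descending variance (ties by catalog order), dropping any feature correlated
at `|r| >= corr_threshold` (default 0.9) with an already-retained one;
zero-variance features are always dropped. The retained fraction is
data-dependent by construction.

## The synthetic scene generator

Scenes emulate the geometry and staining logic of Cell Painting fields, not
their photorealism: non-overlapping elliptical cells (default 12 per
512 × 512 canvas, semi-axes 18-30 px, ≥ 3 px gaps) each contain one interior
elliptical nucleus (35-55% of the cell's scale; containment is guaranteed by
construction in the cell's normalized frame). DNA is bright in nuclei, RNA in
cytoplasm and nuclei, ER/AGP/Mito are textured cytoplasmic signal, and
brightfield planes are mid-gray with edge-weighted darkening. Noise is
Poisson shot noise on the rendered signal plus additive Gaussian read noise
(sigma 100 on the 16-bit scale) — values chosen once as representative of
high-SNR fluorescence imaging. Each scene derives one pseudo-random stream
from `(seed, plate, well, site)`, so manifests of scenes are reproducible
element-wise.

Two artifact knobs support refinement testing. `multi_nucleate_fraction`
plants cells genuinely containing two nuclei, exercising the splitting rule.
Anucleate `fragment_fraction` debris is rendered into the image and into the
cell-class confidence maps but kept out of the ground-truth cell mask — a
fragment is a detection artifact, not a biological object. Merge artifacts
are produced by a separate helper (`merge_cell_pairs`) that fuses the two
closest cells with a connecting bridge, because a merge is a property of a
prediction, not of a scene. What passing tests on these scenes shows is that
the post-processing logic is correct under its assumptions; it does not show
robustness to the texture, debris and focus variability of real microscopy,
which is precisely what a trained segmentation model must supply.

Ideal confidence maps (class = 1 inside objects, border = 1 on 1-px instance
boundaries, optionally blurred) close the loop: segmentation plus refinement
recovers the ground truth exactly (AP = 1 at IoU 0.5 on noise-free scenes),
and outline round-trips recover instance counts exactly with per-instance
IoU ≥ 0.8 — the loss is the 1-px boundary ring, partially restored by
dilation.

## Problem sizes and known limitations

The test suite and acceptance script run scenes of 128-288 px with 3-10
cells and restricted catalogs (2 channels, 4 granularity scales) where full
catalogs are not the point; these sizes keep the whole suite in the tens of
seconds while every code path is still exercised. Full-size fields
(1080 × 1080, hundreds of cells, 8 channels, 442-column catalog) run through
the identical code, only slower — feature extraction is the dominant cost at
roughly 0.2 s per object-compartment with the default catalog.

Limitations: 2-D masks only; no illumination correction; the classical
confidence-map generator is not a substitute for a trained model on crowded
scenes; Costes-style automated colocalization thresholds and image-level QC
features are out of scope; and the train/validation bookkeeping of any
particular upstream dataset (e.g. published split counts that do not sum to
the stated total) is left to the data provider — the manifest implements the
stated selection.
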
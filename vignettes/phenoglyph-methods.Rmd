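---
title: "Methods: glyph encodings, feature extraction and profile analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glyph encodings, feature extraction and profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoglyph)
```

This vignette documents the models, conventions and numerical choices
behind `phenoglyph`: how feature values become glyph geometry, how the
52-feature per-cell table is measured from a two-channel image, how
profiles are compressed, normalized and clustered, and what the synthetic
generators do and do not emulate.

## 1. Feature scaling

Two normalizations coexist, on purpose:

* **Plotting scale.** Dimensional features (cell/nucleus/perinuclear
  lengths and widths) are scaled *jointly*:
  `v' = (v − min)/range × 0.9 + 0.1`, where min and range are taken over
  the pooled values of all dimensional columns. Joint scaling preserves
  the aspect ratios between objects (a nucleus half as long as its cell
  stays half as long), and the 0.1 floor keeps the smallest object
  visible rather than collapsing it to a point. All other bound features
  are min-max scaled per column to `[0, 1]`.
* **Analysis scale.** Clustering and PCA operate on z-scored columns
  (`(x − mean)/sd`), so every feature contributes on the same scale to
  Euclidean distances.

Degenerate inputs follow a midpoint convention: a zero-range column (or a
zero pooled range) maps to the interval midpoint — 0.55 on the
dimensional scale, 0.5 on the unit scale — so constant features render as
mid-size objects instead of failing. A z-scored constant column is an
error, because it carries no distance information. User-supplied values
already outside `[0, 1]` in a pre-scaled table are clipped with a
warning; robust plotting is preferred over a hard failure. Scaling a
table twice is refused (the `scaling` attribute tracks state).

## 2. Glyph geometry

Each glyph lives in a unit box around its anchor; the main ellipse
semi-axes are `0.24 × scaled length/width`, a constant chosen so that the
worst-case glyph (maximal ellipse plus protrusion, spikes and membrane
process) still fits the box, which keeps grid layouts overlap-free by
construction.

Design choices where the visual grammar was open:

* **Border fill is arc-length proportional**, starting at 12 o'clock and
  running clockwise. An angle-proportional arc would over-represent the
  flat regions of an eccentric ellipse; arc length is what the eye reads
  as "how much of the border". Arc positions are computed on a
  2048-point chord table of the ellipse, giving fill fractions accurate
  to well under 1%.
* **Area fill** places symbols on a fixed hexagonal lattice inside the
  region, filling bottom-up until `round(fraction × n_sites)` sites are
  covered. The lattice pitch is derived from the region area so any
  region carries ≈140 sites: the rounding error is below half a percent,
  and the deterministic lattice means identical inputs give
  byte-identical scenes. The region outline is always drawn so partial
  fills can be read by visual closure.
* **Spikes**: triangular, outward, along a contiguous clockwise arc
  covering the bound fraction of the perimeter; 36 spikes ring a full
  border. Maximum spike height is 25% of the minor semi-axis — salient
  without dominating the glyph.
* **Sub-circles** (e.g. nuclei per cell) use a centre-then-ring layout
  with the radius shrinking in the count; a radius floor plus warning
  handles counts beyond the packable maximum.
* **Protrusion** is a half-ellipse on top of the cell whose major
  dimension is `rel_area × main major dimension`; only the major
  dimension is an encoding channel, so its height is fixed at half its
  own major dimension.
* **Organelles** (line, ellipse, rectangle) sit at three fixed slots in
  the lower cytoplasm, between nucleus and border, to avoid occluding
  the nucleus and the protrusion. Fills are *height*-proportional from
  the bottom; for the ellipse organelle the filled region is the segment
  below the cut, so its area follows the circular-segment formula and
  equals half the area exactly at mid-height.
* **Colour** elements map values through the viridis ramp
  (`grDevices::hcl.colors`), perceptually uniform and monotone in
  lightness; most elements are deliberately colour-independent.
* **Membrane process** is rendered as a single stalk on the glyph's left
  side with length proportional to the value. This element is a
  reconstruction: only its name and its presence in the 15-variable
  demonstration configuration are fixed, not its appearance.

The registry composition itself (21 elements, 8 of them
proportional-fill) is a reconstruction constrained by the published
counts and the 15 elements named in the demonstration figure; the exact
upstream element list was not available. Dimensional elements must be
bound as length/width pairs — one without the other cannot participate
in joint scaling — and validation rejects unpaired or doubly-bound
elements by name.

Ellipse outlines defined by a length/width pair are emitted as two
half-arcs, one owned by each binding, so that every bound element owns
exactly one primitive group; unbound elements are simply absent.

## 3. Image-feature extraction

The pipeline measures 52 features per cell: 4 cell morphology, 4 nucleus
morphology, neighbour fraction, protrusion area (absolute and relative),
ruffliness, and 20 texture features per region-channel (nuclear channel
in the nucleus, cell channel in the cell core). The schema is a
reconstruction consistent with the published counts; `feature_schema()`
is the authoritative column order.

**Segmentation.** Nuclei: Otsu threshold on the raw nuclear channel (the
cut is placed at the class-mean midpoint, which is the true edge
position for a blurred step profile), morphological opening, hole
filling, then a distance-transform watershed to split touching nuclei.
Thresholding the *raw* image matters: pre-blurring drags a low threshold
outward and systematically inflates small objects. Cells: hysteresis
thresholding of the cell-body channel — a strong Otsu cut finds bright
cores, a weak cut (Otsu of the sub-threshold population) extends them
into dim protrusions, and weak pixels survive only in components that
contain strong pixels — followed by seeded Voronoi propagation
(`EBImage::propagate`) from the nucleus labels, so each cell contains
its nucleus and touching cells partition their shared foreground.

**Morphology.** Length and width are the major/minor axes of the
second-moment best-fit ellipse (4×√eigenvalues of the pixel-coordinate
covariance). The perimeter is the outer-contour polygon length with
every third vertex retained: the raw 8-connected contour overestimates
smooth boundaries by the staircase effect, and the subsampled polygon
brings a digital disc's form factor `4πA/P²` within a few percent of 1.

**Neighbour fraction.** Border pixels are object pixels with an
8-neighbour outside the object; NF is the fraction of border pixels
whose 8-neighbourhood contains a *different positive* label. Two equal
squares sharing a full edge give NF ≈ 0.26 each (20 contact pixels of a
76-pixel border).

**Core/protrusion split (70% rule).** The threshold is 70% of the mean
cell-channel intensity over the cell mask; the core is the largest
connected component above threshold and everything else in the cell is
protrusion. If no pixel clears the threshold (pathological flat or
negative cells) the whole cell is the core, with a warning.

**SER texture.** Eight features from Gaussian-derivative responses at a
single scale σ = 2 px, averaged over the region, with scale-normalized
derivatives (gradient × σ, curvature × σ²) so feature types are
comparable: `edge` = gradient magnitude; `spot`/`hole` = the
scale-normalized Laplacian (the classic blob detector) gated to pixels
where the Hessian is negative/positive definite; `ridge`/`valley` =
line curvature beyond the blob component; `saddle` = mixed-sign
curvature; `bright`/`dark` = mean positive/negative deviation of the
smoothed intensity from the region mean. All eight vanish on constant
regions, and the derivative features are exactly linear in intensity.
The upstream suite published only the names and count; these definitions
are this package's, chosen so each named structure is the argmax feature
on its canonical stimulus.

**Gabor texture.** A DC-free bank of 4 orientations (0°, 45°, 90°, 135°)
× 2 wavelengths (4, 8 px), σ = 0.56λ; the feature is the mean squared
response magnitude over the region. Rotating the image by 90° permutes
the orientation features exactly.

**Haralick texture.** Region intensities are min-max binned to 32 grey
levels; co-occurrences are counted symmetrically at distance 1 in 4
directions; angular second moment, contrast, correlation and base-2
entropy are computed per direction and averaged. Note that min-max
binning within the region makes these features contrast-normalized: a
flat region plus faint noise still spans all 32 bins, so absolute
contrast values are only comparable between regions of similar dynamic
range.

**Ruffliness** = mean SER edge response over a 3-px membrane band
(mask minus its erosion by a 3-px disc) divided by the cell form factor.
Both terms respond to border irregularity in the same direction. Cells
thinner than the band fall back to the whole cell, with a warning.

**QC.** Mitotic cells are flagged by mean nuclear intensity above
median + 3×MAD per image (the upstream cut-offs were manual per cell
line; a robust per-image default replaces them), small objects by cell
area < 100 px², and border objects by mask contact with the image edge.
All thresholds are arguments. Failed cells (e.g. a nucleus too small for
texture, minimum region 25 px) are dropped with a warning rather than
failing the image.

## 4. Profile analysis

* **Texture index**: each 20-column texture block is min-max scaled,
  then compressed by PCA; the index is the first-PC score. Scaling
  precedes PCA; the assembled profile (morphology + NF + protrusion +
  ruffliness + two texture indices) is then z-scored for clustering.
  PCA signs are arbitrary, so they are fixed deterministically: the
  texture index correlates positively with the mean scaled texture
  magnitude, and each layout PC has its largest-magnitude loading
  positive.
* **Clustering**: Euclidean distance, average linkage (UPGMA), flat cut
  at k; `stats::hclust` is deterministic for tied merges (lowest index
  first). Merge heights are verified in the tests against a brute-force
  O(n³) re-implementation.
* **Cluster mean glyphs** are computed on the *plotting* scale, not the
  z-scored scale — glyphs should show sizes and fractions, not
  standardized deviations.

## 5. Synthetic generators

`synth_cell_image()` renders axis-aligned elliptical cells with a bright
core plateau, an optional dim protrusion plateau occupying an exact
planted fraction of the cell area, interior nucleus ellipses, optional
speckle/grating core texture and Gaussian pixel noise — all a pure
function of the spec including the seed. It emulates the geometry and
intensity structure the pipeline measures (plateaus, contacts, border
objects) but not optical realism: no point-spread function, no
illumination gradients, no out-of-focus light, no intensity-dependent
(Poisson) noise, no irregular cell outlines. Passing segmentation tests
on these fixtures therefore demonstrates correctness of the algorithms
on well-posed inputs, not robustness to real microscopy artefacts.

`synth_feature_table()` draws independent Gaussians around five
archetype mean vectors spanning the phenotype axes the glyphs encode
(round/high-NF; spread/ruffly/protrusive/textured; spread/smooth;
intermediate but most textured; compact/smooth), with per-feature sd
equal to 10% of the across-archetype range — chosen once as a realistic
between-replicate spread for cell-line morphology profiles — and clips
draws to valid domains. Real profile data are correlated across
features; the independence assumption makes the clustering benchmark a
test of the pipeline, not a simulation of biology.

## 6. Problem sizes and determinism

The test-suite and demonstration sizes are: 256×256 px fixture images
with 5 planted cells; 64×64 px oracle images for texture closed forms;
archetype tables of 5 × 20 samples × 9 features, clustered across 20
seeds; brute-force linkage checks at n = 8 and PCA checks at n = 50.
These sizes keep every oracle exactly computable while exercising all
code paths. All randomness is seeded through the generator specs;
rendering contains no randomness at all, and identical inputs produce
byte-identical scenes and SVG files.

## 7. Known limitations

* The element registry, the SER definitions, the 52-feature schema and
  the membrane-process appearance are reconstructions from published
  counts and names (see above); parameters such as the GLCM level count,
  Gabor bank, membrane band width and QC cut-offs are common defaults
  exposed as arguments rather than recovered values.
* Images are single-plane and two-channel; there is no plate/well
  management, illumination correction or 3-D support.
* Coordinate layouts control overlap by shrinking glyphs (median
  nearest-neighbour distance ≥ 1.5 glyph widths); heavily clustered
  layouts can still occlude, and no force-based de-overlap is applied.
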
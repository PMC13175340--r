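---
title: "Cubical persistent homology for image composition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cubical persistent homology for image composition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixtopo)
```

## The model

An 8-bit greyscale image is a matrix of intensities in 0..255. pixtopo
studies it through the **V-construction cubical complex**: one vertex per
pixel, an edge between every pair of 4-neighbours, and a square on every
2×2 pixel block. Each cell enters the filtration at the maximum intensity
of its vertices, so sweeping a threshold `f` from 0 to 255 produces a
nested sequence of 256 complexes. The **BW** (black-to-white) filtration
uses raw intensities — dark structure enters first; **WB** uses `255 − Y`.
Persistent homology tracks connected components (dimension 0) and holes
(dimension 1) across the sweep: each class is a bar `[birth, death)`, the
one component that never dies is the *essential* class, reported with its
death capped at 255.

Two design points matter downstream:

* **Connectivity.** 4-connectivity for pixels, with squares filled as soon
  as all four corners are present. Squares are what kill holes; without
  them dimension-1 classes would never die.
* **Integer lattice.** Intensities are kept as integers and every
  transform rounds half-up exactly once, so births and deaths are always
  integer levels and synthetic scenes can carry exact expected bars.

## Algorithms

Dimension 0 is computed by the standard ascending union-find with the
elder rule (at a merge the earlier-born component survives; ties are
broken by the lexicographic (row, col) position of the component's minimal
vertex, which makes output deterministic). Dimension 1 uses planar
duality: holes of the ascending filtration are connected components of the
complement, so a descending union-find over the dual grid of squares plus
a single outside node yields every bar as (closing-edge value, filling-
square value). Both passes are a few lines of C++ and scale linearly in
practice; a megapixel image takes seconds.

The same pairs can be recomputed by `oracle_persistence()`, a textbook
Z/2 boundary-matrix reduction over the full cell complex. It is quadratic
at best and restricted to small instances; its only purpose is to be an
independent implementation against which the union-find route is tested on
randomized images (the multisets of (dimension, birth, death) must agree
exactly).

**Cycle representatives.** For each dimension-1 bar the package recovers
the hole's complement region at birth — squares with value above the birth
level, connected through edges above the birth level — and returns its
outer boundary, traced with the region kept on the left. Every edge of
that contour is present at the birth level, and the loop provably encloses
at least one pixel that has not yet entered the complex. Representatives
are not unique in homology; this contour convention was chosen because it
is canonical, deterministic, and tight around the feature. An earlier
candidate (closing edge plus shortest path between its endpoints) was
rejected because at birth level the short way round can bound filled
squares, producing a contractible loop.

## Summaries and their conventions

* **Betti curves** count bars alive at each of the 256 levels
  (right-open intervals; the essential class counts through level 255).
  The integrated curve β̄ therefore equals the total persistence of the
  bars, with the essential bar contributing `256 − birth`. This convention
  keeps the duality-violation statistic well defined even for a constant
  image.
* **Persistence landscapes** are evaluated on the integer grid 0..255 —
  the natural 256-point intensity scale — with areas and L1 distances by
  the trapezoid rule. A single bar `(b, d)` has area `(d − b)²/4` exactly
  when `d − b` is even; odd-length bars lose 1/4 per tent because the peak
  falls between grid points. At image scale this discretisation is
  negligible relative to bar counts in the hundreds. Bars with persistence
  ≤ 5 intensity steps are dropped from landscapes by default (the
  threshold used for all group-level summaries); raw pair lists are never
  thresholded.
* **Permutation test.** The group statistic is the L1 distance between the
  two group-mean landscapes, with `p = (1 + #{permuted ≥ observed}) /
  (n_perm + 1)` over 10000 label permutations by default. The statistic is
  one documented choice among reasonable ones (any landscape norm works);
  it is computed by the same code path for observed and permuted labels.
* **ADV.** `adv_bw = (β̄0_BW − β̄1_WB) / mean(β̄0_BW, β̄1_WB)`, and
  symmetrically for `adv_wb`; both lie in [0, 2] because the dimension-0
  area always dominates its dual dimension-1 area. The explicit dual
  *matching* (`match_dual_pairs()`, greedy by descending persistence,
  requiring equal persistence plus spatial overlap between the dimension-0
  anchor and the dimension-1 contour's bounding box) exists to test the
  duality theory bar by bar; the ADV statistic itself never depends on it.

## Feature maps and gaze weighting

Feature maps tile the image with windows of 50 px (the analysis default)
and summarise dimension-1 cycles per window: density counts each cycle
once, in the window holding its contour's bounding-box centroid (an anchor
rule that avoids double counting); maximal persistence and maximal
perimeter are taken over all cycles whose contour touches the window, with
perimeter defined as the number of distinct pixels on the contour. Edge
windows are kept at partial size. Composite maps sum densities and take
maxima across the two filtrations — by duality, dimension-1 cycles of both
directions capture nearly all structure, the exception being
frame-interacting cycles.

Fixation heatmaps deposit an isotropic Gaussian (width `sigma`, default
50 px) at each fixation lasting over 75 ms, with total in-image mass
proportional to duration — the kernel is renormalised inside the image so
border fixations are not penalised by truncation — and the sum normalised
to 1. Window weights integrate the heatmap per window ("looking"); the
complement weighting is uniform over windows with at most `eps = 0.05` of
the maximum window weight ("not looking"). Kernel width, threshold and
normalisation are conventions of this package, recorded in every output.

Weighted ECDFs are compared on the merged support. The reported
`me_looking_vs_notlooking` is oriented so that **positive values mean the
fixated regions carry higher feature values**; because a distribution over
higher values has the *lower* ECDF, this is the negative of the raw mean
ECDF difference. The raw `me_ecdf(e1, e2)` keeps the plain
`mean(e1 − e2)` convention.

## The synthetic generator

`scene_spec()`/`render_scene()` produce images whose complete bar lists
are known in advance: hard-edged, axis-aligned primitives (disk, annulus,
rectangle, frame-touching stripe) strictly darker than the background,
pairwise separated by at least one background pixel, plus an optional
speckle texture of non-overlapping 2×2 dark squares with region-wise
counts. Under these constraints every birth and death is an exact integer
(a disk of intensity `I` on background 255: one BW component `(I, 255)`,
one WB hole `(0, 255 − I)`; an annulus adds the interior hole and interior
component; a full-span stripe splits the background, adding one WB
dimension-0 bar, and has no dual partner). Ambiguous specs — overlapping
or frame-touching primitives — are refused rather than rendered with
unknown truth. Gaussian pixel noise is available for robustness
experiments only and marks the ground truth as inexact.

What the generator deliberately does **not** emulate: anti-aliased edges,
continuous tone gradients, scanner noise, or the long-range intensity
correlations of real paintings. Green tests on synthetic scenes therefore
certify the algorithms and conventions, not the statistical behaviour of
real artworks; the end-to-end group comparison on the study's deposited
stimulus images runs whenever those files are placed under
`inst/stimuli/`.

`simulate_fixations()` picks windows with probability proportional to
`(1 + value)^bias`, uniform positions within the window and uniform
durations — a deliberately minimal observer model (no saccade dynamics, no
centre bias, no temporal correlation).

## Validation conditions and problem sizes

The acceptance suite runs at sizes chosen to make each property sharp yet
quick:

* oracle equivalence and the grid-partition identity on 100 random 8×8
  images (full intensity range for the partition identity, every level
  0..254);
* duality matching on 64×64 scenes with 0–3 frame-touching stripes;
* permutation calibration with two groups of 10 one-bar landscapes and
  999 permutations;
* gaze closure on a 200×200 scene with a 4×4 grid of 50-px windows, a
  high-persistence cluster in one corner window and a faint cluster in the
  opposite one, kernel `sigma = 10` px (the kernel must stay well below
  the image size for a "not-looking" region to exist at all — `sigma = 50`
  is calibrated to full-resolution stimuli, not a 200-px scene), bias 2,
  80 fixations, 100 seeded replicates;
* window-size robustness on a 1010×1010 four-patch speckle texture
  (region densities 200/600/1800/5400), comparing per-pixel density ECDFs
  at windows 51 and 101. The texture's density varies on a scale larger
  than either window: that is the regime in which window choice is claimed
  not to matter. On a spatially homogeneous texture the comparison is
  dominated by Poisson sampling noise, whose relative width shrinks with
  window area, and the ECDFs differ for that reason alone;
* contrast robustness via gamma 0.8 and 1.25 on a blob-and-speckle scene:
  monotone maps preserve pixel order, so thresholded bar counts are
  unchanged even though persistences shrink or stretch.

## Known limitations

* Only dimensions 0 and 1, 2-D images, 8-bit intensity; no point clouds
  and no colour-aware (chromatic) complexes — RGB channels can be analysed
  one at a time as greyscale planes.
* Landscape areas are trapezoid approximations on the integer grid (exact
  for even-length bars).
* The dual matching is greedy; with many equal-persistence bars in
  overlapping regions a valid matching could in principle be missed,
  though equal persistence plus spatial overlap disambiguates all
  generator scenes.
* `read_image()` supports PNG and TIFF input.
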
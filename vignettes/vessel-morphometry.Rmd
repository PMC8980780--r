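---
title: "Retinal vessel morphometry from segmentation masks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel morphometry from segmentation masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmetrics)
```

## What the package measures

`vesselmetrics` turns co-registered binary artery, vein and optic-disc
segmentation masks of a fundus photograph into a hierarchical vessel graph and
computes, per image:

* **standard-zone summaries** — the central retinal artery and vein
  equivalents (CRAE, CRVE) from the six largest vessels of each class in the
  annulus 0.5-1.0 disc diameters outward from the disc margin, and their
  ratio AVRe;
* **per-segment physical parameters** — diameter profile (mean, SD), arc
  length, chord length, length-diameter ratio (LDR), tortuosity;
* **per-bifurcation geometry** — trunk and daughter calibers, branching
  angle from centerlines (BA) and from wall contours (BA_edge), branching
  coefficient BC, angular asymmetry AA, asymmetry ratio AR, and the
  junctional exponent deviation JED from Murray's law;
* **topology** — centrifugal vessel orders and Strahler orders on the graph
  rooted at the optic disc, plus a box-counting fractal dimension;
* **quality control** — exclusion of images with no detectable disc, fewer
  than six arteries or six veins in the standard zone, or fewer than two
  arteries or two veins in the whole fundus.

All calibers and lengths are reported in **pixel units**. Fundus cameras vary
in magnification, most are not telecentric, and without refraction data a
micron conversion is spurious precision; ratios (AVRe, LDR, tortuosity, BC,
AR, JED) are unit-free and transfer across cameras.

Coordinates are 1-based `(row, col)` with pixel centers at integer positions,
the native R matrix convention, used consistently everywhere.

## From masks to a graph

1. **Preprocessing.** Masks are cropped to the bounding box of the field of
   view and resized to a square analysis frame (default 512 px) with
   nearest-neighbor interpolation. Nearest-neighbor is a deliberate choice:
   it keeps masks strictly binary, whereas area-weighted resampling creates
   fractional labels. The interpolation used by the upstream segmentation
   systems is typically unspecified; nearest-neighbor is this package's
   choice.
2. **Skeletonization.** The union of the artery and vein masks is thinned to
   a one-pixel, 8-connected skeleton (Zhang-Suen two-subiteration thinning).
   The union is essential: an artery-vein crossing only exists as a
   degree-4 node in the union; class masks individually pass straight
   through each other. Enclosed background components of up to 12 px
   (pinholes where several strokes nearly meet, common in real masks too)
   are filled first: a pinhole forces the skeleton into a spurious loop.
   Genuine enclosed regions of a vessel mesh are far larger and survive.
3. **Node classification.** Skeleton pixels are classified by the
   *transition number* of their 8-neighbor ring (number of 0-to-1
   transitions): 1 = endpoint, 2 = regular, 3+ = junction. The raw neighbor
   count is unreliable here — a pixel on a 45-degree staircase has three
   neighbors yet lies mid-path. Residual thick clumps of the thinning
   (4+ neighbors forming a 2x2 block) are also treated as junction pixels.
   Adjacent junction pixels are merged into clusters (thinning emits
   junction *blobs*, not single pixels); each cluster becomes one node at
   its centroid, with kind assigned from the number of incident segments
   (3 = bifurcation, 4+ = crossing).
4. **Segment tracing.** Maximal skeleton paths between nodes become
   segments. A diagonal adjacency between two path pixels that flank a
   common junction pixel is severed first — otherwise the four arms of an X
   fuse pairwise. Segments shorter than `min_segment_len = 10` centerline
   points are excluded (length in points, i.e. pixels, not Euclidean arc).
5. **Class assignment.** Each segment votes its class by majority membership
   of its centerline in the artery versus vein mask.
6. **Crossings.** At each crossing node, incident same-class segments are
   paired by most-collinear end tangents (near-ties broken by caliber
   similarity) and marked as continuations of one vessel path. Orders do
   not increment across a crossing — a vessel passing over another is not a
   branching — and vessel identity for zone counting merges continuation
   pairs, so one anatomical vessel is counted once.
7. **Orders.** Segments with an endpoint within 1.1 disc radii of the disc
   center root the graph (the rooting rule is this package's construction).
   Centrifugal vessel order increments at bifurcations. Strahler order is
   assigned bottom-up: leaves are 1; a parent whose children attain their
   maximal order twice at a bifurcation gets that order plus one.

## Caliber estimation

Caliber at a centerline point is `2 * EDT - 1`, where EDT is the Euclidean
distance transform of the class mask, read as the **maximum over the point's
3x3 neighborhood**. The thinned skeleton tracks the true medial axis only to
within about a pixel; reading the EDT exactly at the skeleton pixel
underestimates tilted vessels by roughly half a pixel, while the local
maximum recovers the medial radius. For an odd-width straight stroke the
estimate is exact.

Junction blobs inflate the distance transform over a reach that scales with
the local caliber, so profile points within `max(2, EDT at the node)` path
steps of a junction-attached end are excluded. A fixed two-pixel exclusion
is not enough under a 10-pixel trunk. Bifurcation calibers `d0, d1, d2` are
means of the valid profile points nearest the node — a local estimate,
robust to taper along the segment (window size below).

Tangents at nodes (for branching angles and crossing pairing) are the
principal direction of `tangent_window = 15` centerline points starting just
past the exclusion zone; five-point digital lines quantize direction by
several degrees, which is why the window is this long. At a bifurcation the
two daughters additionally skip the initial run where their strokes are
merged with each other (detected as centerline separation below the sum of
the half-calibers): inside that run the thinned centerline follows the
merged wedge, not either vessel's own axis, and including it inflates
narrow branching angles by tens of degrees. Bifurcation calibers use the
same merged-run skip, and average `node_caliber_window = 12` valid points
(about one to two vessel diameters) — enough that the Murray-law residual
is not dominated by per-point caliber noise.

Tortuosity is the simple arc-to-chord index; arc length is the sum of
Euclidean steps along the centerline. The 8-connected chain slightly
overestimates the length of smooth curves (the staircase effect, up to a few
percent at unfavorable orientations); this propagates into tortuosity and
LDR and is a known limitation of chain-code arc length. The exact formulas
used by reference-tool pipelines are unpublished; the arc/chord index and
the EDT caliber are isolated behind single functions so either can be
substituted.

`BA_edge` re-estimates each daughter direction from total-least-squares line
fits to its two wall contours within 10 px of the node (walls located by
subpixel ray marching from the centerline), then averages the two wall
directions per daughter. On straight-walled daughters it agrees with the
centerline angle to within ~3 degrees.

JED is `((d1^3 + d2^3)^(1/3) - d0) / d0` — the total, monotone form of the
Murray residual. Solving `d0^x = d1^x + d2^x` for the junctional exponent
itself was rejected because no root exists whenever `d0 <= max(d1, d2)`,
which happens regularly under measurement noise.

## Standard zone and vessel equivalents

The disc is the largest connected component of the disc mask, summarized by
its centroid and equivalent-area radius `r`. The standard zone is the
annulus `[2r, 3r]` (margin + 0.5 to 1.0 disc diameters). Each distinct
vessel path crossing the zone contributes the mean caliber of its in-zone
centerline points (mean-inside-zone is this package's choice; a single-point
caliber would be noisier). The six largest enter the revised pairwise
combination: sort, combine widest with narrowest as `c * sqrt(w1^2 + w2^2)`
with `c = 0.88` for arteries and `0.95` for veins, carry the median when the
count is odd, repeat until one value remains. A single remaining input is
returned unchanged — the constants apply per pairing, not to lone widths.
AVRe = CRAE / CRVE.

## Quality control

An image is excluded if the disc is undetectable, if either class has fewer
than six distinct vessels in the standard zone, or fewer than two in the
whole fundus. The zone rule is read as requiring *both* classes to reach
six — symmetric with the whole-fundus clause; the source phrasing is
ambiguous and this reading is the stricter one. Excluded images keep every
computable measurement and are written to a separate output with their
reasons, so exclusions remain auditable.

## Agreement statistics

`pixel_metrics()` computes AUC by the Mann-Whitney rank statistic (ties
averaged) plus accuracy, sensitivity, specificity and F1 at a 0.5 threshold,
evaluated **inside the field of view only** — background outside the fundus
circle would inflate specificity. `icc_agreement()` is the two-way
random-effects, absolute-agreement, single-measurement ICC — the standard
test-retest form — with McGraw-Wong confidence bounds, banded as poor
(< 0.5), moderate (0.5-0.75), good (0.75-0.9), excellent (>= 0.9).
`bland_altman()` reports the mean paired difference and mean ± 1.96 SD
limits of agreement.

## The synthetic retina

Because real fundus datasets and a trained segmentation network are outside
this package's scope, every measurement is validated on a parameterized
synthetic retina with exhaustive ground truth (`synth_tree_spec()`,
`generate_tree()`). Defaults describe a disc-centered eye on a 512-px frame:

* disc of radius `image_side / 12` (~43 px) at the center;
* three artery trunks and three vein trunks interleaved at 60-degree
  spacing around the disc, so that peripheral branches of adjacent fans
  cross and the union mask contains genuine artery-vein crossings;
* trunk calibers 9 px (arteries) and 11.25 px (veins) — a realistic
  arteriolar/venular caliber at this frame size, with veins ~25% wider;
* four generations, calibers tapering by Murray's law at exponent 3,
  segment lengths starting at 1.5 disc radii and shrinking by 0.8 per
  generation (the first bifurcation falls inside the standard zone, giving
  nine distinct zone vessels per class — comfortably above the
  quality-control minimum of six);
* a 70-degree nominal branching angle with ±3 degrees of jitter, and a
  sinusoidal centerline perturbation of amplitude 0.8 px (one period per
  segment) — mild, realistic tortuosity (~1.01);
* optional `len_ratio` and `branch_angle_ratio` decay factors (defaults 0.8
  and 1). The angle decay exists for controlled-topology studies: a full
  binary tree with a constant 70-degree angle genuinely self-intersects
  from about five generations, so deep single-tree validation uses a
  per-generation angle shrink to keep the embedding planar.

The truth tables record, per segment: the nominal caliber, arc, chord,
tortuosity (integrated numerically from the dense polyline, not assumed
closed-form), vessel and Strahler orders; per bifurcation: calibers, the
*actual* branching angle between the analytic daughter tangents (jitter and
sinusoid included), deviation angles and JED.

**Realized calibers.** A binary grid cannot draw a 4.5-px stroke: stamping
discs of radius `w/2` along the centerline quantizes an axial stroke to the
nearest odd width. The truth therefore records, next to the nominal
caliber, the caliber the rasterization *realizes* (`width_realized`,
measured on the analytic centerline of the isolated stroke, and the JED it
implies). Recovery of the drawn image is judged against the realized
values; nominal values are still recovered to within a pixel. The stamp
radius `w/2` (pixel centers strictly inside the stroke) was chosen over
`(w-1)/2` because the latter under-draws fractional calibers by up to 1.5
px; with `w/2`, odd integer widths rasterize exactly and the caliber
estimator recovers them without error.

`make_repeat_pair()` emulates repeat photography of the same eye: the same
tree rasterized twice, the second time under a small rigid motion bounded by
`jitter_px`. Repeatability studies vary the root caliber across simulated
eyes (uniform 7-11 px), since reliability coefficients are meaningless
without between-subject variance.

What the generator does **not** emulate: segmentation noise (broken or
merged vessels), pathology, central light reflex, caliber taper within a
segment, image blur. Passing the synthetic battery therefore demonstrates
correctness of the measurement chain on clean masks, not robustness to
segmentation failure modes.

## Validation batteries and problem sizes

The test suite validates, among others: the pairwise-combination rule
against an independently coded recursion (1000 random caliber sets) and
hand-iterated values; caliber, branching-angle, tortuosity and JED recovery
pooled over 100 seeded default trees (mean caliber error vs. drawn truth
~0.2 px, vs. nominal ~0.45 px; pooled branching-angle bias ~1 degree; mean
|JED error| < 0.05); graph orders against brute-force recursion on full
binary trees to depth 5 and caterpillar topologies; the QC gate against
exhaustive enumeration of its domain; AUC against brute-force pair
enumeration; ICC against a frozen external reference fixture and simulated
variance components; CRAE/CRVE repeat-imaging ICC over 20 jittered pairs
(excellent band); and byte-identical pipeline reruns. These sizes were
chosen to make Monte-Carlo noise small relative to each tolerance while
keeping a full run in minutes on one core.

## Known limitations

* Chain-code arc length overestimates smooth curve length by up to ~5%,
  inflating tortuosity and LDR slightly; a subpixel smoothing of the
  centerline would remove this and is isolated behind `arc_length()`.
* Single-junction calibers quantize by up to a pixel on the grid, so
  per-junction BC/AR/JED carry noise of that order at calibers below ~8 px;
  distribution-level summaries are stable (and are what the batteries
  assert).
* Vessels thinner than ~2 px skeletonize but their calibers saturate at 1.
* Images whose vessel trees detach from the disc neighborhood (e.g.
  macula-centered crops missing the disc) leave components unrooted; their
  segments carry measurements but no orders, and QC normally excludes such
  images anyway.
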
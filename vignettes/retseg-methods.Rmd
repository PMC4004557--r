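---
title: "Dual-threshold entropy vessel segmentation and width measurement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-threshold entropy vessel segmentation and width measurement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `retseg`, the parameters that
matter, the numerical choices made where the method leaves them open, and
what the synthetic phantoms do and do not demonstrate about real fundus
images.

## The segmentation model

A colour fundus photograph shows the retinal vasculature as dark,
curvilinear structures on the green channel, inside a bright circular
field of view (FOV). The pipeline makes three structural assumptions:

* vessels are *ridges*: elongated structures whose intensity profile has a
  strong second derivative across and a weak one along the vessel;
* the vessel/background decision can be made globally on the gray-level
  transition statistics of the top-hat image, i.e. a co-occurrence
  maximum-entropy threshold, applied at two scales (a permissive scale for
  the vessel mask, a strict one for the bright reflex cores);
* background noise is spatially organised: some areas of the image are
  dominated by fine speckle, others by coarse blobs, so the
  smallest-component size worth keeping differs by region.

### Preprocessing and FOV

The green channel has the best vessel/background contrast. The *black
top-hat* (closing minus image, disk radius `preprocess.tophat_radius`,
range 10–60, default 30 px) turns dark vessels into bright ridges and
removes smooth illumination; everything downstream assumes this bright
polarity. The FOV mask is computed from the Sobel gradient magnitude
(Otsu-thresholded by default, `fov.sobel_threshold`), closed with twelve
3-px line elements at 15° steps, hole-filled, and reduced to the largest
component.

### Ridge enhancement

`hessian_eigen()` computes the Gaussian-derivative Hessian at a single
scale `enhance.sigma` (default 1.5 px, matching the 1–10 px caliber range
of fundus vessels at DRIVE-like resolution; deliberately single-scale, no
scale-space maximum). The sampled derivative kernels are renormalised so
the discrete operators are exact on quadratics (`sum(g2) = 0`,
`sum(x² g2) = 2`, `sum(x g1) = -1`); without this the eigenvalues of an
analytic test surface are biased by a few tenths of a percent.
`vesselness()` is the standard two-term 2-D Frangi response with
`beta = 0.5` and `c = "auto"` (half the maximum Frobenius norm of the
Hessian over the image), zeroed where `λ₂ ≥ 0`. Both terms are kept; the
blobness term suppresses isotropic structures (pathology spots), the
structure term suppresses flat background.

### Co-occurrence entropy thresholding

The quantized top-hat image (`entropy.L`, default 255) yields a
co-occurrence matrix of right- and below-neighbour transitions. For a
candidate threshold `t` the matrix splits into within-background
(`i ≤ t, j ≤ t`), within-object (`i > t, j > t`) and two cross quadrants.
Each quadrant's probabilities are renormalised within the quadrant and its
second-order entropy is `-(1/2) Σ p̂ log₂ p̂` (the ½ factor and log base
do not affect the argmax; they are fixed for reproducibility).

**Cross-quadrant terms are included in the maximised total by default**
(`optimal_threshold(include_cross = TRUE)`). This was a genuinely open
design point, and the diagonal-only variant fails structurally: for any
image with a bimodal histogram, a threshold outside the two modes leaves
one quadrant holding *both* modes, whose renormalised entropy then
contains the full inter-mode bit and dominates every between-mode
threshold. Measured on the bimodal test image (modes 3 and 12 of 15, 5%
salt), the diagonal-only total peaks at t = 14; the four-quadrant total
peaks at t = 4, inside the modes, which is the behaviour a thresholding
rule must have. The exposed `h_total` column remains the object +
background sum, and `h_cross` is reported separately.

Two binarisation regimes share the optimal threshold `t*`: the mask
regime (`entropy.mask_scale`, range 0.3–0.8, default 0.5) feeds the
multiplication with the enhanced image; the reflex regime
(`entropy.reflex_scale`, range 0.8–3, default 1.5) recovers the bright
central-light-reflex cores of large vessels. `entropy.reflex_channel`
can switch the reflex source to the luminance of the colour image.

### Texture partition

The partition uses an oriented complex (Gabor) wavelet bank — six
orientations at `texture.levels` dyadic scales (default 3, base
wavelength 3 px) — as the texture feature transform. Magnitudes are
median-filtered (`texture.median_size`) and then pooled with a Gaussian
window (`texture.pool_sigma`, default 8 px, about the coarse-granule
radius). Pooling matters: without it, flat background pixels *between*
noise granules carry no texture signal at all and are indistinguishable
across texture regions; with it every pixel estimates its local texture
energy.

The watershed floods the Sobel gradient of the summed subbands after a
disk closing (`texture.hminima_radius`) with minima shallower than
`texture.hminima` suppressed. Both values are calibration points with no
stated value in the method's source; the defaults here (radius 4,
h = 0.02 on the [0,1]-normalised gradient) were chosen so that the stage
actually *over*-segments (tens of regions on a 256² frame) — larger
settings collapse the tiling to a handful of regions that straddle
texture boundaries, after which no clustering can recover them.

Region similarity uses a Gaussian kernel on standardised features with
median-distance bandwidth. The features are subband *energy proportions*
(plus mean intensity and log area): raw magnitudes track local contrast
rather than spectral shape, and regions of equal texture but different
contrast would otherwise repel. Spectral clustering is a normalized cut:
row-normalised leading eigenvectors of `D^{-1/2} W D^{-1/2}` grouped by a
deterministic k-means (farthest-first seeding with value-based
tie-breaks, then Lloyd) — deterministic and invariant to node order, and
verified in the tests against an exhaustive minimum-normalized-cut oracle
on a ten-node two-clique graph. `texture.k` (default 8) is the pre-merge
cluster count.

The merge to two labels is automatic (the original protocol adjusted a
threshold by hand, which is not reproducible): each cluster is summarised
by the median granule area over its bright pixels (granules = connected
components above the in-FOV Otsu threshold; the per-pixel median weights
granules by the area they contribute inside the cluster, so neither many
small speckles nor one straddling blob can tip a cluster), and an exact
1-D two-means split of the log sizes separates fine from coarse. Clusters
with less than 2% bright-pixel support defer to the feature-space nearest
labelled group. A manual override map (`texture.override`) is accepted.

### Routing, connectivity and fusion

Image class is assigned manually (class 1 = uniform illumination with
well-localised reflex, steps 2+5; class 2 = uniform illumination with
reflex-broken vessels, steps 2+3+5; class 3 = non-uniform illumination and
pathology, steps 1–5). The connectivity filter removes 8-connected
components not larger than the threshold of the texture label covering
the majority of their pixels (`segment.min_fine` = 5,
`segment.min_coarse` = 16; a single global `min_fine` when no partition
exists). The reflex segmentation is computed on the whole top-hat image
and cleaned with the coarse constraint before the OR of step 5 —
restricting it to the coarse texture label starves wide vessels that
cross the fine-textured part of the frame. Step 5 closes the union with
a radius-2 disk and clips to the FOV.

## Width measurement

The mask is thinned (Zhang–Suen), reduced to minimal 8-connected paths
(deleting pixels whose neighbours remain mutually 8-connected without
them; this removes the 4-connected staircases thinning leaves on oblique
lines, which would otherwise read as branch points), and pruned of spurs
shorter than 3 px. Measurement candidates are centreline pixels with
exactly two neighbours forming a path with distinct coordinates along at
least one axis; the 14-window catalogue covers the exactly-one-axis
paths, and straight diagonals (distinct along both axes) are kept via the
orientation-group tie-break, so 45° vessels remain measurable. Branch
pixels are rejected, which is what makes the method robust at vessel
crossings.

Coordinates are 1-based `(x = column, y = row)` with y downward —
the R convention; the 90° counter-clockwise rotation is
`(dx, dy) → (dy, −dx)`. The perpendicular profile steps one pixel along
its dominant axis (no sub-pixel sampling), stops at the first background
pixel (`width.gap_tolerance` = 0 by default), and the width is the
Euclidean edge-to-edge distance plus one. The +1 pixel-extent term makes
the Euclidean and pixel-count definitions agree exactly on axis-aligned
bars; on diagonal profiles the discrete step length (√2) under-corrects
slightly, which bounds the error at ±1.5 px over the tested 3–11 px
width range (mean absolute error ≈ 0.32 px, measured by the acceptance
script).

## Width-evaluation protocol

Marked edge-point pairs are closed into solid segments with a square
element whose side `s` auto-escalates (cap 15) until each declared vessel
is a single, hole-free component — hole-freeness matters because a pair of
parallel edge chains closed with a too-small element leaves a hollow core
that is still one component. Success requires the nearest predicted
centre within the local true width and inside the closed ground-truth
segment. The mean width is closed-segment pixels divided by thinned
centreline pixels; thinning shortens the centreline at segment ends, so
the ratio is biased slightly upward on short segments (about +0.6 px on a
100-px bar; negligible on vessel-length segments). The error standard
deviation is `sqrt(Σ e_l² / n_lines)` over cross-section lines drawn
*through* each edge-point pair (extended by half the pair distance on
each side, so that a prediction wider than the ground truth still
intersects its line).

## The phantom generator

`generate_phantom()` emulates the features the pipeline is sensitive to:
a bright circular FOV (radius 0.45·min(H, W)); 6 vessels of width 3–9 px
drawn as quadratic Bézier curves (tortuosity 0.15 of chord length) with
trapezoidal cross-sections 0.35 intensity units darker than the 0.65
background; an optional 1-px brighter core line at half the vessel
contrast (the central light reflex); a ±20% multiplicative diagonal
illumination gradient; two bright pathology blobs (radius 8–16 px); and
dark noise granules — fine (2 px, 4% coverage) confined to the left half
and coarse (12 px, 8% coverage) to the right, so the texture partition
has an unambiguous ground truth. Coverage means the expected fraction of
the half-frame occupied by granules; the values are set so each half is
visibly dominated by its noise type, which is the condition the
texture-adaptive constraint exists for. Truth tables (gold mask,
centreline widths every ~3 px, REVIEW-style edge-point pairs every ~2 px,
partition map, FOV) are exact by construction, and everything is
bit-reproducible from the seed.

What passing on phantoms does *not* show: real fundus images have
vessel-adjacent texture (choroidal background, optic disc, macula),
JPEG artifacts, and noise that is not half-plane-organised. The phantom
validates the algorithmic contracts — polarity handling, threshold
behaviour, localisation, the size-adaptive filtering logic — not clinical
performance. The half-plane noise layout in particular gives the
partition a crisp ground truth at the cost of realism; a mixed layout
exercises robustness but has no truth label.

## Problem sizes and degenerate inputs

Tests and the acceptance script use 256² phantoms (three instances for the
end-to-end rates), 32² images for entropy oracles, 72² bars for width
recovery, and a 10-node graph for the exhaustive normalized-cut oracle.
Degenerate inputs are contracts, not errors: a blank image yields an
all-true FOV with a warning; a constant gradient one watershed region; a
flat entropy profile threshold 0 with a warning; a scaled threshold above
the maximum level an empty mask with a warning; an empty mask an empty
centreline and an empty record table. Ties break deterministically: the
smallest threshold at equal entropy, the first cluster centre in a fixed
value order, the smallest record index in the width-evaluation
association.

## Known limitations

* Single-scale ridge enhancement under-responds in the interior of
  vessels much wider than `enhance.sigma`; the reflex-regime binarisation
  compensates, but very wide, low-contrast vessels remain the main source
  of false negatives.
* The automatic fine/coarse merge substitutes a reproducible criterion
  for a manual protocol; on images whose granule-size distribution is
  unimodal it labels everything fine (with a warning) and the filter
  degrades to a single global constraint.
* Width records are pixel-quantised; no sub-pixel edge localisation is
  attempted, and widths at exactly 45° are quantised in steps of √2.
* The optic disc is not detected or suppressed; bright disc edges can
  survive as false positives in class-1/2 routing on real images.
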
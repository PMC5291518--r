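---
title: "Quantifying cerebral microbleeds in stained coronal sections"
author: "microbleedR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral microbleeds in stained coronal sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbleedR)
```

## The problem

Neonatal germinal-matrix and periventricular hemorrhages appear in stained
coronal brain sections as compact clusters of extravasated blood whose
colour differs sharply from the surrounding tissue. Manual outlining of
these microbleeds is slow and observer-dependent, so microbleedR automates
the measurement chain: per-pixel blood classification, per-bleed
morphometry, region-of-interest (ROI) quantification of immunolabeling, and
group statistics. Because studies of this kind rarely deposit raw images,
the package also ships a synthetic histology generator with exact ground
truth, so the entire chain is verifiable by simulation.

## Blood-pixel classification

For each RGB section the green and blue channels are isolated; the red
channel carries little contrast between blood and counterstained tissue and
is discarded. Each pixel is a point $x = (g, b) \in [0, 255]^2$, and blood
detection is a two-class linear classification

$$\hat{y}(x) = \mathrm{sign}(w \cdot x + b_0),$$

with blood on the positive side and ties ($w \cdot x + b_0 = 0$) assigned
to non-blood, a deliberately conservative blood call.

Training pixels (blood-positive and blood-negative) are taken from a single
designated section containing extravasated blood, mirroring practice in
which an investigator hand-selects examples once and applies the classifier
to the whole batch. The working premise is that the two colour clusters are
*linearly separable with zero training error*, so the default fit is the
hard-margin maximum-margin separator. In two dimensions this has an exact
geometric solution: the maximum-margin hyperplane of two separable point
sets is the perpendicular bisector of the closest pair of points between
their convex hulls, and the geometric margin is half that distance.
`trainClassifier()` computes this closest pair directly from hull geometry
(segment-to-segment distances plus hull-containment tests), which is exact
up to floating point — no iterative solver, no tolerance knobs. If the
hulls touch or overlap, the premise is violated and the fit *fails loudly*;
a conventional soft-margin fit (linear-kernel SVM) is available behind the
explicit `mode = "soft"` flag and is never engaged silently.

Features are raw 8-bit intensities, unnormalized: a maximum-margin linear
boundary is covariant under affine rescaling of the feature axes, and no
normalization rule is assumed. No post-hoc mask cleanup (despeckling,
morphological closing) is applied at the classification stage; speckle
suppression happens transparently downstream via the `minPixels` filter.

## Microbleed morphometry

A classified mask decomposes into maximal 8-connected components, each one
microbleed. 8-connectivity was chosen because blood blobs are compact and
diagonally adjacent blood pixels almost surely belong to one extravasation;
the synthetic generator guarantees 8-connected ground-truth bleeds, so
truth and measurement use the same topology. Components below `minPixels`
(default 2 pixels) are discarded to suppress single-pixel classifier
speckle; with `minPixels = 1` the summed component areas equal the total
masked area exactly, a conservation law the test suite asserts on random
masks. Component labels follow column-major first encounter and are
deterministic.

Per bleed the package reports the calibrated area $A$ (pixel count
$\times$ pixel size$^2$, in $\mu m^2$), the centroid (pixel centres, in
$\mu m$; 0-based indices, origin top-left, x rightward, y downward), and
the circular-equivalent diameter

$$d = 2\sqrt{A/\pi},$$

the diameter of the circle with the same area. Reported integer diameters
use round-half-up. Aggregations follow the conventions of the hemorrhage
literature: per-plane totals (coronal planes 0.5 mm apart, offsets measured
caudally from the rostral tip of the lateral ventricles), size-frequency
histograms with half-open uniform bins anchored at 0 (default width
500 $\mu m^2$, so the first bin is the 0–500 $\mu m^2$ class of smallest
bleeds), and spatial bleed maps in which the two hemispheres are folded
onto one side by reflecting centroids across a vertical midline
($x' = m + |x - m|$) and entries are drawn largest-first.

Whether a "mean bleed size" should pool bleeds across animals or average
per-animal means is a genuine reporting ambiguity; the package computes
whichever the caller assembles from the bleed table and the statistics
layer treats *the animal* as the unit of analysis (per-animal values are
means over that animal's sections) to avoid pseudo-replication.

## ROI quantification of specific labeling

Specific immunolabeling is quantified as the percent of an ROI whose
intensity strictly exceeds twice a background level ("% ROI"). The
threshold is exactly $2\times$ background and the inequality is strict —
a pixel at exactly twice background is negative. ROIs are rectangles,
ovals, or circles specified in micrometres and rasterized at pixel centres;
rectangles use half-open intervals so that a rectangle whose sides are
multiples of the pixel size covers exactly its nominal pixel count, and
ellipse membership is $(x/a)^2 + (y/b)^2 \le 1$. Rasterized areas agree
with analytic areas to well under 2% for ROIs $\ge$ 100 px across.

How "background" should be measured is not standardized; the package makes
the background region an explicit user input (a label-free region of the
image) and estimates background as its median — the lower middle order
statistic for even counts, so the estimate is always an observed intensity.
The relevant channel must be named for multi-channel input; it is never
inferred.

## Group statistics

Reporting follows the field's conventions: per-group mean $\pm$ SE (sample
sd with $n-1$ denominator over $\sqrt{n}$), classical equal-variance
one-way ANOVA ($F$ on $k-1$, $N-k$ degrees of freedom), Tukey HSD
studentized-range post-hoc pairwise comparisons, and fold changes of group
means reported both raw and rounded half-up to integer for "$n$-fold"
phrasing. ANOVA and Tukey are delegated to R's `aov()`/`TukeyHSD()`; the
test suite checks them against a permutation oracle and a Monte-Carlo
studentized-range oracle, confirms the nominal type-I error rate under
null simulation, and verifies that Tukey-adjusted p values dominate the
unadjusted pooled-variance (Fisher LSD) pairwise p values — the
comparison for which dominance is a theorem (a two-sample t-test with its
own two-group variance estimate can occasionally fall above the Tukey p).

## The synthetic generator: what it emulates

`generateSection()` paints a tissue-coloured field, places bleeds as
rasterized discs perturbed by random boundary dilation (each bleed one
8-connected component; bleeds never touch, so ground truth decomposes
exactly), and draws every pixel's colour from the Gaussian cluster of its
truth class. Default study conditions:

* **Calibration**: 2 $\mu m$/pixel (magnifications in this literature are
  rarely reported; at this scale a 0–500 $\mu m^2$ bleed spans 10–125
  pixels — small images, resolvable bleeds). Field 512 $\times$ 512 px
  ($\approx$ 1 mm$^2$), a periventricular field of view rather than a
  whole hemisphere.
* **Bleed sizes**: all groups carry a small-bleed component, uniform on
  [38, 500] $\mu m^2$ (mean 269; the PS-AD variant uses [180, 500], mean
  340). Only the injured vaginal-delivery group (PS-VD) carries a large
  component — Gamma(shape 4) with mean 7339 $\mu m^2$ at mixture weight
  0.4 — so the PS-VD mixture mean is
  $0.6 \times 269 + 0.4 \times 7339 = 3097\ \mu m^2$. These reproduce the
  structure reported for this injury model: small bleeds everywhere, large
  bleeds only after vaginal delivery with prenatal pro-angiogenic stimuli,
  and an order-of-magnitude difference in mean bleed size.
* **Bleed counts**: Poisson, $\lambda = 1$ per field for control-like
  groups and $\lambda = 10/3$ for PS-VD, making small bleeds twice as
  frequent in PS-VD ($0.6 \times 10/3 = 2$) as in controls.
* **Colours**: tissue mean RGB (230, 185, 195) — pale eosin pink, high
  green and blue; blood mean (150, 45, 50) — dense heme, low green and
  blue; per-channel sd 8, clipped to [0, 255]. The (g, b) cluster centres
  sit $\approx$ 200 intensity units apart against sd 8, so every training
  set of practical size is linearly separable with a wide margin (the
  suite checks separability with an independent SVM oracle up to $10^4$
  pixels).
* **Placement**: centres drawn from a 2-D Gaussian around a configurable
  periventricular anchor (fractional position (0.45, 0.35), sd 0.2 of the
  field) — a declared stand-in for the reported periventricular
  predominance, for which no coordinates exist. In crowded scenes the
  sampler falls back to uniform placement over the in-bounds region after
  repeated collisions rather than failing, and errors only when a bleed
  genuinely cannot fit.

Disc centres are continuous, so the expected rasterized pixel count equals
the target area; the random dilation (each outside 4-neighbour added with
probability 0.15) enlarges bleeds by a few percent of their perimeter,
a small, documented upward bias ($\approx$ 1% for large bleeds) well
inside the recovery tolerances the tests assert. Recorded ground truth is
always the *painted* mask, so conservation (painted pixels $\times$ pixel
size$^2$ = summed truth areas) is exact by construction.

`generateFluorescenceImage()` produces the complementary fixture for the
ROI rule: a single-channel image in which an exact number of pixels —
`round(fraction × npixels)` — sits at a known positive level over a flat
background, with optional clipped Gaussian noise, and the realized
fraction recorded as truth.

What the generator does **not** emulate: stain-deconvolution physics,
illumination gradients, tissue texture and edge artefacts, anatomical
boundaries (ventricle lumina, meninges), partial-volume colour mixing at
bleed rims, or 3-D continuity of bleeds across sections. Passing the
synthetic suites therefore demonstrates that the measurement chain is
correct *given* the colour-cluster model; it does not certify classifier
performance on real slides, where the separability premise itself must be
re-checked (and the hard-margin fit will refuse to proceed if it fails).

## Problem sizes and numerical choices

The verification suites run at the scales the package's own accuracy
arguments require: 100 independently generated training sets for the
zero-training-error property; margin agreement with a brute-force
direction-search oracle (8192-angle grid plus local refinement) to three
significant figures on point sets of up to 20; 200 full-size PS-VD
sections for detection fidelity (per-section area within 5% of painted
truth; recovered mean bleed area within 3 standard errors of the
configured mixture mean); 1000 random 64 $\times$ 64 masks against a
brute-force flood-fill labeling oracle; and $4 \times 10^4$ null
replicates for the ANOVA type-I rate, which pins the Monte-Carlo standard
error of the estimated size near 0.001. Degenerate inputs fail explicitly
everywhere: inseparable training data, single-class samples, empty
background regions, empty ROIs, out-of-bounds ROIs, mixed-plane bleed
tables, groups of fewer than two values, and zero within-group variance
all raise errors naming the offending condition rather than returning
quietly wrong numbers.

## A worked miniature

```{r example}
cfg <- sceneConfig("PS-VD", imageSize = c(256L, 256L), seed = 42L)
sec <- generateSection(cfg)
train <- sampleTrainingPixels(sec, nPos = 60, nNeg = 60, seed = 1L)
boundary <- trainClassifier(train)
boundary

res <- analyzeSection(sectionImage(sec), boundary)
res$total_area_um2
sum(bleedTruth(sec)$area_um2)          # painted truth, for comparison
head(res$bleeds[, c("pixel_count", "area_um2", "diameter_um")])
```

## Limitations

The classifier is a single global linear boundary per batch: colour drift
across staining batches, illumination changes, or non-blood chromogens
with blood-like (g, b) signatures will degrade it, and batch-wise
retraining is the intended remedy (colour normalization across batches is
out of scope). Morphometry is strictly 2-D — bleeds spanning adjacent
sections are counted per section, not reconstructed. ROI anchors are
manual micrometre coordinates; no atlas registration is attempted.
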
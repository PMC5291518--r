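# microbleedR

Automated, unbiased quantification of cerebral microbleeds in RGB images of
stained coronal brain sections, written for studies of neonatal germinal
matrix / periventricular hemorrhage where bleeds must be detected, sized and
compared across experimental groups without manual outlining.

The measurement chain:

1. **Blood-pixel detection.** Each pixel's (green, blue) intensities form a
   2-D feature; the red channel is discarded. A **hard-margin linear SVM**
   is trained on hand-labeled blood / non-blood pixels from a single
   designated section: for linearly separable classes the maximum-margin
   separator `sign(w·x + b)` is computed *exactly* as the perpendicular
   bisector of the closest pair of points between the two class convex
   hulls (margin = half that distance), and training error is 0 by
   construction. Non-separable input raises an error — the zero-error
   premise is never silently relaxed (an explicit soft-margin fallback
   exists behind `mode = "soft"`).
2. **Microbleed morphometry.** The blood mask decomposes into maximal
   8-connected components (Rcpp); each bleed gets a calibrated area
   *A* = pixels × (µm/pixel)², a centroid, and a circular-equivalent
   diameter *d* = 2√(A/π). Aggregations: per-plane totals across coronal
   planes 0.5 mm apart, size-frequency histograms with half-open 500-µm²
   bins anchored at 0, and spatial bleed maps with hemispheres folded
   across the midline.
3. **ROI quantification.** Specific immunolabeling is the percent of an
   ROI (rectangle / oval / circle, µm units) whose intensity *strictly*
   exceeds 2× a background level estimated as the median of a
   user-designated label-free region.
4. **Group statistics.** Mean ± SE per group, classical one-way ANOVA,
   Tukey HSD post-hoc pairwise comparisons, and fold changes of group
   means (raw and integer-rounded, half-up).

A synthetic histology generator (`sceneConfig()` / `generateSection()` /
`generateFluorescenceImage()`) produces calibrated sections with exact
ground truth — painted blood masks, per-bleed records, known positive
fractions — so every stage is verifiable without the original tissue
images. See the vignette in `vignettes/microbleed-quantification.Rmd` for
the model, the generator's default study conditions, and known limitations.

## Worked example

```r
library(microbleedR)

cfg <- sceneConfig("PS-VD", imageSize = c(256L, 256L), seed = 42L)
sec <- generateSection(cfg)                       # synthetic injured section
train <- sampleTrainingPixels(sec, nPos = 60, nNeg = 60, seed = 1L)
(boundary <- trainClassifier(train))
#> LinearBoundary (hard margin)
#>   w = (-0.6555, -0.7552), b = 164.5
#>   geometric margin = 81.66, training error = 0

res <- analyzeSection(sectionImage(sec), boundary)
res$total_area_um2                                # detected blood area
#> [1] 7664
sum(bleedTruth(sec)$area_um2)                     # painted ground truth
#> [1] 7664
head(res$bleeds[, c("pixel_count", "area_um2", "diameter_um")])
#>   pixel_count area_um2 diameter_um
#> 1          67      268    18.47236
#> 2         111      444    23.77642
#> 3        1534     6136    88.38890
#> 4         123      492    25.02866
#> 5          60      240    17.48077
#> 6          21       84    10.34177
```

The trained boundary separates the blood and tissue colour clusters with a
wide margin and zero training error; on this section the detected blood
area equals the painted truth exactly, and the bleed table shows the
typical injured-group mixture — several sub-500-µm² microbleeds plus one
large hemorrhage (6136 µm², equivalent diameter 88 µm).

The same arithmetic applied to published group means:

```r
equivalentDiameter(c(269, 3097, 340))     # mean bleed areas, um^2
#> [1] 18.50679 62.79509 20.80628          # print as 19, 63, 21 um
foldChange(2744, 270)                     # mean total areas, um^2
#> $ratio
#> [1] 10.16296
#> $fold
#> [1] 10                                  # "a 10-fold increase"
```

A thin command-line wrapper over the same functions is provided in
`inst/scripts/microbleed-cli.R` (subcommands `simulate`, `train`,
`detect`, `quantify`, `roi-quant`, `stats`; see its header for usage).

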
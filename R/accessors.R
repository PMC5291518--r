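#' @rdname SectionImage-class
#' @param pixels numeric array (H x W x C, C in {1, 3}), intensities in
#'   [0, 255].
#' @param pixelSize micrometres per pixel.
#' @param planeOffset coronal plane offset in mm.
#' @param animalId,groupLabel identifiers.
#' @return \code{SectionImage()} returns a \linkS4class{SectionImage}.
#' @export
SectionImage <- function(pixels, pixelSize = 2, planeOffset = NA_real_,
                         animalId = NA_character_,
                         groupLabel = NA_character_) {
    if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
    new("SectionImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
        planeOffset = as.numeric(planeOffset),
        animalId = as.character(animalId),
        groupLabel = as.character(groupLabel))
}

#' Accessors for microbleedR objects
#'
#' @param object a microbleedR S4 object.
#' @return \code{pixelSize} the spatial calibration in um/pixel;
#'   \code{imagePixels} the intensity array; \code{planeOffset} the coronal
#'   plane in mm; \code{maskMatrix} the logical blood mask; \code{groupLabel}
#'   the experimental group.
#' @examples
#' img <- SectionImage(array(0, dim = c(2, 2, 3)), pixelSize = 2)
#' pixelSize(img)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "SectionImage", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "BloodMask", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SceneConfig", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setMethod("imagePixels", "SectionImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("imagePixels", "SyntheticSection",
    function(object) object@image@pixels)

#' @rdname accessors
#' @export
setGeneric("planeOffset", function(object) standardGeneric("planeOffset"))
#' @rdname accessors
#' @export
setMethod("planeOffset", "SectionImage", function(object) object@planeOffset)
#' @rdname accessors
#' @export
setMethod("planeOffset", "BloodMask", function(object) object@planeOffset)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "BloodMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskMatrix", "SyntheticSection", function(object) object@bloodTruth)

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setMethod("groupLabel", "SectionImage", function(object) object@groupLabel)
#' @rdname accessors
#' @export
setMethod("groupLabel", "SceneConfig", function(object) object@groupLabel)
#' @rdname accessors
#' @export
setMethod("groupLabel", "SyntheticSection",
    function(object) object@image@groupLabel)

#' @rdname accessors
#' @export
setGeneric("sectionImage", function(object) standardGeneric("sectionImage"))
#' @rdname accessors
#' @export
setMethod("sectionImage", "SyntheticSection", function(object) object@image)

#' @rdname accessors
#' @export
setGeneric("bleedTruth", function(object) standardGeneric("bleedTruth"))
#' @rdname accessors
#' @export
setMethod("bleedTruth", "SyntheticSection", function(object) object@bleedTruth)

#' @rdname accessors
#' @export
setGeneric("labelFractionTruth",
    function(object) standardGeneric("labelFractionTruth"))
#' @rdname accessors
#' @export
setMethod("labelFractionTruth", "SyntheticSection",
    function(object) object@labelFractionTruth)

#' @rdname accessors
#' @export
setGeneric("sampleFeatures", function(object) standardGeneric("sampleFeatures"))
#' @rdname accessors
#' @export
setMethod("sampleFeatures", "PixelSampleSet", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setMethod("sampleLabels", "PixelSampleSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("boundaryWeights",
    function(object) standardGeneric("boundaryWeights"))
#' @rdname accessors
#' @export
setMethod("boundaryWeights", "LinearBoundary", function(object) object@w)

#' @rdname accessors
#' @export
setGeneric("boundaryBias", function(object) standardGeneric("boundaryBias"))
#' @rdname accessors
#' @export
setMethod("boundaryBias", "LinearBoundary", function(object) object@b)

#' @rdname accessors
#' @export
setGeneric("boundaryMargin", function(object) standardGeneric("boundaryMargin"))
#' @rdname accessors
#' @export
setMethod("boundaryMargin", "LinearBoundary", function(object) object@margin)

#' @rdname accessors
#' @export
setGeneric("trainingError", function(object) standardGeneric("trainingError"))
#' @rdname accessors
#' @export
setMethod("trainingError", "LinearBoundary",
    function(object) object@trainingError)

#' @rdname accessors
#' @export
setGeneric("groupSummary", function(object) standardGeneric("groupSummary"))
#' @rdname accessors
#' @export
setMethod("groupSummary", "GroupComparison", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("tukeyTable", function(object) standardGeneric("tukeyTable"))
#' @rdname accessors
#' @export
setMethod("tukeyTable", "GroupComparison", function(object) object@tukey)

#' @rdname accessors
#' @export
setGeneric("foldChanges", function(object) standardGeneric("foldChanges"))
#' @rdname accessors
#' @export
setMethod("foldChanges", "GroupComparison", function(object) object@foldChanges)

#' @rdname accessors
#' @export
setGeneric("anovaF", function(object) standardGeneric("anovaF"))
#' @rdname accessors
#' @export
setMethod("anovaF", "GroupComparison", function(object) object@anovaF)

#' @rdname accessors
#' @export
setGeneric("anovaP", function(object) standardGeneric("anovaP"))
#' @rdname accessors
#' @export
setMethod("anovaP", "GroupComparison", function(object) object@anovaP)

#' @rdname accessors
#' @export
setGeneric("positiveAreaFraction",
    function(object) standardGeneric("positiveAreaFraction"))
#' @rdname accessors
#' @export
setMethod("positiveAreaFraction", "LabelQuantification",
    function(object) object@positiveAreaFraction)

setMethod("show", "SectionImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("SectionImage: %d x %d px, %d channel(s), %.3g um/px\n",
        d[1], d[2], d[3], object@pixelSize))
    if (!is.na(object@planeOffset))
        cat(sprintf("  plane: %.2f mm caudal to rostral ventricle tip\n",
            object@planeOffset))
    if (!is.na(object@groupLabel))
        cat(sprintf("  animal: %s  group: %s\n", object@animalId,
            object@groupLabel))
})

setMethod("show", "BloodMask", function(object) {
    cat(sprintf(
        "BloodMask: %d x %d px, %d blood-positive (%.4g um^2 at %.3g um/px)\n",
        nrow(object@mask), ncol(object@mask), sum(object@mask),
        sum(object@mask) * object@pixelSize^2, object@pixelSize))
})

setMethod("show", "LinearBoundary", function(object) {
    cat(sprintf("LinearBoundary (%s margin)\n", object@mode))
    cat(sprintf("  w = (%.4g, %.4g), b = %.4g\n", object@w[1], object@w[2],
        object@b))
    cat(sprintf("  geometric margin = %.4g, training error = %.4g\n",
        object@margin, object@trainingError))
})

setMethod("show", "PixelSampleSet", function(object) {
    tab <- table(object@labels)
    cat(sprintf("PixelSampleSet: %d blood, %d non-blood samples in (g, b)\n",
        tab[["blood"]], tab[["non-blood"]]))
})

setMethod("show", "SceneConfig", function(object) {
    cat(sprintf("SceneConfig [%s]: %d x %d px at %.3g um/px, plane %.2f mm\n",
        object@groupLabel, object@imageSize[1], object@imageSize[2],
        object@pixelSize, object@planeOffset))
    d <- object@bleedAreaDist
    cat(sprintf(
        "  bleeds ~ Poisson(%.3g); area: U(%g, %g) um^2 (w = %.2g) + Gamma(mean %g) (w = %.2g)\n",
        object@nBleedsMean, d$smallMin, d$smallMax, 1 - d$largeWeight,
        d$largeMean, d$largeWeight))
    cat(sprintf("  seed = %d\n", object@seed))
})

setMethod("show", "SyntheticSection", function(object) {
    d <- dim(object@image@pixels)
    cat(sprintf("SyntheticSection: %d x %d px, %d ground-truth bleed(s)\n",
        d[1], d[2], nrow(object@bleedTruth)))
    if (!is.na(object@labelFractionTruth))
        cat(sprintf("  fluorescence mode, label fraction truth = %.4g\n",
            object@labelFractionTruth))
})

setMethod("show", "ROISpec", function(object) {
    cat(sprintf("ROISpec '%s': %s %g x %g um at (%g, %g) um\n",
        object@name, object@shape, object@width, object@height,
        object@anchor[1], object@anchor[2]))
})

setMethod("show", "LabelQuantification", function(object) {
    cat(sprintf(
        "LabelQuantification '%s': %.2f%% ROI > 2 x background (%g -> threshold %g), %d px\n",
        object@roiName, object@positiveAreaFraction, object@backgroundLevel,
        object@threshold, object@nPixels))
})

setMethod("show", "GroupComparison", function(object) {
    cat("GroupComparison (mean +/- SE; one-way ANOVA + Tukey HSD)\n")
    s <- object@summary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-8s n = %2d  %.4g +/- %.3g\n", s$group[i], s$n[i],
            s$mean[i], s$se[i]))
    cat(sprintf("  ANOVA: F = %.4g, p = %.3g\n", object@anovaF, object@anovaP))
})
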
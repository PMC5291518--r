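#' @import methods
NULL

#' Calibrated section image
#'
#' An RGB (or single-channel fluorescence) raster of a stained coronal brain
#' section together with its spatial calibration and plane metadata.
#' Intensities are 8-bit (0--255) stored as numeric.
#'
#' @slot pixels numeric array, height x width x channels (channels 1 or 3),
#'   values in [0, 255].
#' @slot pixelSize numeric(1), micrometres per pixel (> 0).
#' @slot planeOffset numeric(1), coronal plane position in mm caudal to the
#'   rostral tip of the lateral ventricles.
#' @slot animalId character(1) identifier.
#' @slot groupLabel character(1) experimental group label.
#'
#' @examples
#' img <- SectionImage(array(128, dim = c(4, 4, 3)), pixelSize = 2)
#' pixelSize(img)
#' @export
setClass("SectionImage",
    representation(
        pixels = "array",
        pixelSize = "numeric",
        planeOffset = "numeric",
        animalId = "character",
        groupLabel = "character"
    ),
    prototype(
        pixelSize = 2,
        planeOffset = NA_real_,
        animalId = NA_character_,
        groupLabel = NA_character_
    )
)

setValidity("SectionImage", function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (length(d) != 3L) {
        msg <- c(msg, "'pixels' must be a 3-d array (height x width x channels)")
    } else if (!d[3] %in% c(1L, 3L)) {
        msg <- c(msg, "'pixels' must have 1 or 3 channels")
    }
    if (length(object@pixelSize) != 1L || is.na(object@pixelSize) ||
        object@pixelSize <= 0) {
        msg <- c(msg, "'pixelSize' must be a single positive number")
    }
    rng <- suppressWarnings(range(object@pixels))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 255)) {
        msg <- c(msg, "pixel intensities must lie in [0, 255]")
    }
    if (length(msg)) msg else TRUE
})

#' Labeled pixel training samples
#'
#' Hand-selected (or synthetically sampled) blood-positive and blood-negative
#' pixels carrying their (green, blue) intensity features.
#'
#' @slot features numeric matrix, n x 2, columns \code{g} and \code{b},
#'   values in [0, 255].
#' @slot labels factor of length n with levels \code{blood}, \code{non-blood}.
#' @export
setClass("PixelSampleSet",
    representation(features = "matrix", labels = "factor")
)

setValidity("PixelSampleSet", function(object) {
    msg <- character()
    if (ncol(object@features) != 2L)
        msg <- c(msg, "'features' must have two columns (g, b)")
    if (nrow(object@features) != length(object@labels))
        msg <- c(msg, "'features' rows and 'labels' length differ")
    if (!identical(levels(object@labels), c("blood", "non-blood")))
        msg <- c(msg, "'labels' levels must be c('blood', 'non-blood')")
    if (nrow(object@features) &&
        (min(object@features) < 0 || max(object@features) > 255))
        msg <- c(msg, "features must lie in [0, 255]")
    if (length(msg)) msg else TRUE
})

#' Linear decision boundary in the (green, blue) plane
#'
#' The maximum-margin separator between blood and non-blood pixel classes.
#' A pixel with features x = (g, b) is called blood iff w . x + b > 0
#' (ties classify as non-blood).
#'
#' @slot w numeric(2), weights on (g, b); \code{||w|| > 0}.
#' @slot b numeric(1), bias.
#' @slot margin numeric(1), geometric margin (>= 0), the minimum distance
#'   from any training sample to the boundary.
#' @slot trainingError numeric(1) in [0, 1]; exactly 0 for a hard-margin fit.
#' @slot mode character(1), \code{"hard"} or \code{"soft"}.
#' @export
setClass("LinearBoundary",
    representation(
        w = "numeric",
        b = "numeric",
        margin = "numeric",
        trainingError = "numeric",
        mode = "character"
    ),
    prototype(mode = "hard")
)

setValidity("LinearBoundary", function(object) {
    msg <- character()
    if (length(object@w) != 2L || sqrt(sum(object@w^2)) <= 0)
        msg <- c(msg, "'w' must be a 2-vector with ||w|| > 0")
    if (length(object@margin) != 1L || object@margin < 0)
        msg <- c(msg, "'margin' must be a single number >= 0")
    if (object@trainingError < 0 || object@trainingError > 1)
        msg <- c(msg, "'trainingError' must lie in [0, 1]")
    if (!object@mode %in% c("hard", "soft"))
        msg <- c(msg, "'mode' must be 'hard' or 'soft'")
    if (length(msg)) msg else TRUE
})

#' Per-pixel blood classification mask
#'
#' @slot mask logical matrix, TRUE where a pixel is blood-positive.
#' @slot pixelSize numeric(1), micrometres per pixel of the source image.
#' @slot planeOffset numeric(1), plane of the source image (mm).
#' @slot animalId,groupLabel character(1), carried from the source image.
#' @export
setClass("BloodMask",
    representation(
        mask = "matrix",
        pixelSize = "numeric",
        planeOffset = "numeric",
        animalId = "character",
        groupLabel = "character"
    ),
    prototype(
        planeOffset = NA_real_,
        animalId = NA_character_,
        groupLabel = NA_character_
    )
)

setValidity("BloodMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask))
        msg <- c(msg, "'mask' must be a logical matrix")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Synthetic scene configuration
#'
#' Parameters of the synthetic histology generator. Defaults depend on the
#' experimental group and emulate the structure the analysis assumes: small
#' microbleeds (area below 500 um^2) in every group, a heavy large-bleed
#' mixture component only in the injured vaginal-delivery group (PS-VD), and
#' periventricular spatial bias. See \code{\link{sceneConfig}}.
#'
#' @slot groupLabel character(1), one of CTR-VD, mLPS-VD, PS-VD, PS-AD.
#' @slot imageSize integer(2), height and width in pixels.
#' @slot pixelSize numeric(1), um/pixel.
#' @slot planeOffset numeric(1), mm caudal to the rostral ventricle tip.
#' @slot nBleedsMean numeric(1), Poisson mean of the bleed count (>= 0).
#' @slot bleedAreaDist list with elements \code{smallMin}, \code{smallMax}
#'   (uniform small-bleed component, um^2), \code{largeWeight} (mixture
#'   weight of the large component, 0 for all groups but PS-VD by default),
#'   \code{largeMean}, \code{largeShape} (gamma large component).
#' @slot tissueColor,bloodColor list with \code{mean} (RGB, length 3) and
#'   \code{sd} (per-channel standard deviation) of the Gaussian colour
#'   cluster.
#' @slot spatialBias list with \code{anchor} (ventricle anchor, fraction of
#'   (height, width)) and \code{sd} (placement sd, fraction of image size).
#' @slot seed integer(1) RNG seed.
#' @export
setClass("SceneConfig",
    representation(
        groupLabel = "character",
        imageSize = "integer",
        pixelSize = "numeric",
        planeOffset = "numeric",
        nBleedsMean = "numeric",
        bleedAreaDist = "list",
        tissueColor = "list",
        bloodColor = "list",
        spatialBias = "list",
        seed = "integer"
    )
)

setValidity("SceneConfig", function(object) {
    msg <- character()
    if (!object@groupLabel %in% c("CTR-VD", "mLPS-VD", "PS-VD", "PS-AD"))
        msg <- c(msg, "unknown 'groupLabel'")
    if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
        msg <- c(msg, "'imageSize' must be two integers >= 8")
    if (object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be > 0")
    if (object@nBleedsMean < 0)
        msg <- c(msg, "'nBleedsMean' must be >= 0")
    d <- object@bleedAreaDist
    if (!all(c("smallMin", "smallMax", "largeWeight", "largeMean",
               "largeShape") %in% names(d)))
        msg <- c(msg, "'bleedAreaDist' is missing components")
    else if (d$largeWeight < 0 || d$largeWeight > 1)
        msg <- c(msg, "'largeWeight' must lie in [0, 1]")
    for (nm in c("tissueColor", "bloodColor")) {
        cl <- slot(object, nm)
        if (!all(c("mean", "sd") %in% names(cl)) ||
            length(cl$mean) != 3L || any(cl$mean < 0) || any(cl$mean > 255))
            msg <- c(msg, sprintf("'%s' must have RGB mean in [0,255] and sd", nm))
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic section with ground truth
#'
#' A generated \linkS4class{SectionImage} together with the truth that makes
#' every downstream stage verifiable: the painted blood mask, the per-bleed
#' ground-truth table, and (for fluorescence images) the exact fraction of
#' positively labeled pixels.
#'
#' @slot image a \linkS4class{SectionImage}.
#' @slot bloodTruth logical matrix congruent with the image.
#' @slot bleedTruth data.frame with one row per painted bleed (id,
#'   centroid_x_um, centroid_y_um, pixel_count, area_um2, target_area_um2,
#'   component).
#' @slot labelFractionTruth numeric(1) in [0, 1]; NA outside fluorescence
#'   mode.
#' @slot config the \linkS4class{SceneConfig} used (empty list-like config
#'   for fluorescence images).
#' @export
setClass("SyntheticSection",
    representation(
        image = "SectionImage",
        bloodTruth = "matrix",
        bleedTruth = "data.frame",
        labelFractionTruth = "numeric",
        config = "ANY"
    ),
    prototype(labelFractionTruth = NA_real_)
)

setValidity("SyntheticSection", function(object) {
    msg <- character()
    d <- dim(object@image@pixels)
    if (!identical(dim(object@bloodTruth), d[1:2]))
        msg <- c(msg, "'bloodTruth' is not congruent with the image")
    px <- object@image@pixelSize
    painted <- sum(object@bloodTruth) * px^2
    if (is.na(object@labelFractionTruth)) {
        # histology mode: painted mask and bleed table must agree exactly
        if (nrow(object@bleedTruth)) {
            if (abs(painted - sum(object@bleedTruth$area_um2)) > 1e-6)
                msg <- c(msg, "painted truth area != sum of bleed truth areas")
        } else if (painted != 0) {
            msg <- c(msg, "painted pixels exist but bleed truth table is empty")
        }
    }
    if (!is.na(object@labelFractionTruth) &&
        (object@labelFractionTruth < 0 || object@labelFractionTruth > 1))
        msg <- c(msg, "'labelFractionTruth' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Region-of-interest specification
#'
#' Geometric ROI in micrometre units: an axis-aligned rectangle, an oval
#' inscribed in its w x h bounding box, or a circle of a given diameter.
#' The anchor is the ROI centre in micrometre image coordinates
#' (x rightward, y downward, origin at the top-left image corner).
#'
#' @slot shape character(1), \code{"rectangle"}, \code{"oval"} or
#'   \code{"circle"}.
#' @slot width,height numeric(1), um; for a circle both equal the diameter.
#' @slot anchor numeric(2), ROI centre (x, y) in um.
#' @slot name character(1) label.
#' @export
setClass("ROISpec",
    representation(
        shape = "character",
        width = "numeric",
        height = "numeric",
        anchor = "numeric",
        name = "character"
    )
)

setValidity("ROISpec", function(object) {
    msg <- character()
    if (!object@shape %in% c("rectangle", "oval", "circle"))
        msg <- c(msg, "'shape' must be rectangle, oval or circle")
    if (object@width <= 0 || object@height <= 0)
        msg <- c(msg, "ROI dimensions must be positive")
    if (object@shape == "circle" && object@width != object@height)
        msg <- c(msg, "a circle must have width == height (the diameter)")
    if (length(object@anchor) != 2L)
        msg <- c(msg, "'anchor' must be (x, y) in um")
    if (length(msg)) msg else TRUE
})

#' Specific-labeling quantification for one ROI
#'
#' Result of the segmentation-analysis rule: the percent of ROI area whose
#' intensity strictly exceeds twice the background level.
#'
#' @slot roiName character(1).
#' @slot backgroundLevel numeric(1) intensity.
#' @slot threshold numeric(1), exactly 2 x backgroundLevel.
#' @slot positiveAreaFraction numeric(1), percent of ROI in [0, 100].
#' @slot nPixels integer(1), ROI size in pixels.
#' @export
setClass("LabelQuantification",
    representation(
        roiName = "character",
        backgroundLevel = "numeric",
        threshold = "numeric",
        positiveAreaFraction = "numeric",
        nPixels = "integer"
    )
)

setValidity("LabelQuantification", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@threshold, 2 * object@backgroundLevel)))
        msg <- c(msg, "'threshold' must equal 2 x backgroundLevel exactly")
    if (object@positiveAreaFraction < 0 || object@positiveAreaFraction > 100)
        msg <- c(msg, "'positiveAreaFraction' must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Group comparison report
#'
#' Per-group mean and standard error, one-way ANOVA, Tukey HSD post-hoc
#' pairwise comparisons, and pairwise fold changes of group means.
#'
#' @slot summary data.frame with columns group, n, mean, se.
#' @slot anovaF,anovaP numeric(1), the ANOVA F statistic and p value.
#' @slot tukey data.frame with columns group_a, group_b, diff, p_adj.
#' @slot foldChanges numeric matrix of pairwise mean ratios
#'   (rows / columns); the diagonal is 1.
#' @export
setClass("GroupComparison",
    representation(
        summary = "data.frame",
        anovaF = "numeric",
        anovaP = "numeric",
        tukey = "data.frame",
        foldChanges = "matrix"
    )
)

setValidity("GroupComparison", function(object) {
    msg <- character()
    if (!all(c("group", "n", "mean", "se") %in% colnames(object@summary)))
        msg <- c(msg, "'summary' must have columns group, n, mean, se")
    if (!is.na(object@anovaP) && (object@anovaP < 0 || object@anovaP > 1))
        msg <- c(msg, "'anovaP' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
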
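# ROI-based quantification of specific labeling: percent of ROI area whose
# intensity strictly exceeds 2 x background.

#' Construct an ROI specification
#'
#' @param shape \code{"rectangle"}, \code{"oval"} or \code{"circle"}.
#' @param width,height extent in um (rectangle sides or oval bounding-box
#'   axes); for a circle give \code{diameter} instead.
#' @param diameter circle diameter in um.
#' @param anchor ROI centre (x, y) in um image coordinates.
#' @param name label recorded in outputs.
#' @return a validated \linkS4class{ROISpec}.
#' @examples
#' roiSpec("rectangle", width = 1500, height = 500, anchor = c(2000, 800))
#' roiSpec("circle", diameter = 500, anchor = c(1000, 1000))
#' @export
roiSpec <- function(shape = c("rectangle", "oval", "circle"), width = NULL,
                    height = NULL, diameter = NULL, anchor, name = shape) {
    shape <- match.arg(shape)
    if (shape == "circle") {
        if (is.null(diameter)) stop("a circle ROI needs 'diameter'")
        width <- height <- diameter
    }
    if (is.null(width) || is.null(height))
        stop("'width' and 'height' are required for ", shape, " ROIs")
    new("ROISpec", shape = shape, width = as.numeric(width),
        height = as.numeric(height), anchor = as.numeric(anchor),
        name = as.character(name))
}

#' Rasterize an ROI onto an image grid
#'
#' Converts a micrometre-space ROI into a boolean pixel raster. A pixel
#' belongs to the ROI iff its centre does: rectangles use half-open
#' intervals [c - w/2, c + w/2) on each axis (so a rectangle whose sides are
#' integer multiples of the pixel size covers exactly w/px x h/px pixels);
#' ovals and circles use the inscribed-ellipse test
#' (x/a)^2 + (y/b)^2 <= 1 at pixel centres.
#'
#' @param spec an \linkS4class{ROISpec}.
#' @param image a \linkS4class{SectionImage} supplying grid and calibration.
#' @return logical matrix congruent with the image.
#' @export
rasterizeROI <- function(spec, image) {
    stopifnot(is(spec, "ROISpec"), is(image, "SectionImage"))
    validObject(spec)
    px <- image@pixelSize
    d <- dim(image@pixels)
    H <- d[1]; W <- d[2]
    cx <- spec@anchor[1]; cy <- spec@anchor[2]
    hw <- spec@width / 2; hh <- spec@height / 2
    lo <- c(cx - hw, cy - hh); hi <- c(cx + hw, cy + hh)
    if (lo[1] < 0 || lo[2] < 0 || hi[1] > W * px || hi[2] > H * px)
        stop(sprintf(
            "ROI '%s' extends beyond the image: x [%.1f, %.1f], y [%.1f, %.1f] um vs image %g x %g um",
            spec@name, lo[1], hi[1], lo[2], hi[2], W * px, H * px))
    xc <- (seq_len(W) - 0.5) * px      # pixel-centre x per column
    yc <- (seq_len(H) - 0.5) * px      # pixel-centre y per row
    if (spec@shape == "rectangle") {
        inx <- xc >= lo[1] & xc < hi[1]
        iny <- yc >= lo[2] & yc < hi[2]
        outer(iny, inx, "&")
    } else {
        outer(((yc - cy) / hh)^2, ((xc - cx) / hw)^2, "+") <= 1
    }
}

#' Estimate the background intensity of a label-free region
#'
#' Median intensity over a user-designated background region. For an even
#' pixel count the lower middle order statistic is taken, so the estimate is
#' always an observed intensity.
#'
#' @param image a \linkS4class{SectionImage}.
#' @param backgroundRegion logical matrix congruent with the image, TRUE
#'   over the label-free region.
#' @param channel channel index used for intensity (default 1).
#' @return numeric(1) background intensity.
#' @export
estimateBackground <- function(image, backgroundRegion, channel = 1L) {
    stopifnot(is(image, "SectionImage"))
    d <- dim(image@pixels)
    if (!identical(dim(backgroundRegion), d[1:2]))
        stop("'backgroundRegion' is not congruent with the image")
    vals <- image@pixels[, , channel][backgroundRegion]
    if (!length(vals)) stop("background region is empty")
    sort(vals)[ceiling(length(vals) / 2)]    # lower median for even counts
}

#' Percent of ROI with specific labeling
#'
#' Applies the segmentation rule for specific labeling: a pixel is positive
#' iff its intensity strictly exceeds twice the background level (intensity
#' exactly equal to 2 x background is negative). Returns the percent of ROI
#' pixels that are positive (% ROI).
#'
#' @param image a \linkS4class{SectionImage}.
#' @param roi logical ROI raster (from \code{\link{rasterizeROI}}) or an
#'   \linkS4class{ROISpec} to be rasterized.
#' @param backgroundLevel background intensity (>= 0), e.g. from
#'   \code{\link{estimateBackground}}.
#' @param channel channel index used for intensity (default 1).
#' @param name ROI label for the report (defaults to the ROISpec's name or
#'   \code{"roi"}).
#' @return a \linkS4class{LabelQuantification}.
#' @examples
#' fl <- generateFluorescenceImage(40, 0.25, 200,
#'                                 imageSize = c(64L, 64L), seed = 5)
#' roi <- matrix(TRUE, 64, 64)
#' positiveAreaFraction(percentPositive(sectionImage(fl), roi, 40))
#' @export
percentPositive <- function(image, roi, backgroundLevel, channel = 1L,
                            name = NULL) {
    stopifnot(is(image, "SectionImage"))
    if (backgroundLevel < 0) stop("'backgroundLevel' must be >= 0")
    if (is(roi, "ROISpec")) {
        if (is.null(name)) name <- roi@name
        roi <- rasterizeROI(roi, image)
    }
    d <- dim(image@pixels)
    if (!identical(dim(roi), d[1:2]))
        stop("ROI raster is not congruent with the image")
    n <- sum(roi)
    if (n == 0L) stop("ROI is empty")
    vals <- image@pixels[, , channel][roi]
    npos <- sum(vals > 2 * backgroundLevel)
    new("LabelQuantification",
        roiName = if (is.null(name)) "roi" else name,
        backgroundLevel = as.numeric(backgroundLevel),
        threshold = 2 * as.numeric(backgroundLevel),
        positiveAreaFraction = 100 * npos / n,
        nPixels = as.integer(n))
}
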
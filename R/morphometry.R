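# Microbleed morphometry: individual bleeds as 8-connected components of the
# blood mask, calibrated areas and circular-equivalent diameters, per-plane
# totals, size-frequency histograms, hemisphere-folded spatial maps.

emptyBleedTable <- function() {
    data.frame(id = integer(), animal_id = character(),
               group = character(), plane_mm = numeric(),
               pixel_count = integer(), area_um2 = numeric(),
               centroid_x_um = numeric(), centroid_y_um = numeric(),
               diameter_um = numeric())
}

#' Extract individual microbleeds from a blood mask
#'
#' Labels maximal 8-connected components of blood-positive pixels and
#' returns one record per component: pixel count, calibrated area,
#' intensity-free centroid (pixel centres, um) and circular-equivalent
#' diameter. Components smaller than \code{minPixels} are discarded
#' (classifier speckle suppression); with \code{minPixels = 1} the summed
#' component areas equal the total masked area exactly. Component ids follow
#' column-major first encounter and are stable across runs.
#'
#' Coordinates are 0-based with origin at the top-left corner, x rightward
#' (columns) and y downward (rows); the centre of pixel (i, j) is at
#' ((j + 0.5), (i + 0.5)) pixel units, converted to um by the pixel size.
#'
#' @param mask a \linkS4class{BloodMask}.
#' @param minPixels minimum component size in pixels (default 2).
#' @return data.frame with columns id, animal_id, group, plane_mm,
#'   pixel_count, area_um2, centroid_x_um, centroid_y_um, diameter_um.
#' @export
extractBleeds <- function(mask, minPixels = 2) {
    stopifnot(is(mask, "BloodMask"))
    m <- mask@mask
    if (!any(m)) return(emptyBleedTable())
    lab <- label_components_8(m)
    idx <- which(lab > 0)
    comp <- lab[idx]
    counts <- tabulate(comp)
    rows <- (idx - 1L) %% nrow(m)        # 0-based row index
    cols <- (idx - 1L) %/% nrow(m)       # 0-based column index
    sumR <- rowsum(as.numeric(rows), comp)[, 1]
    sumC <- rowsum(as.numeric(cols), comp)[, 1]
    keep <- which(counts >= minPixels)
    if (!length(keep)) return(emptyBleedTable())
    px <- mask@pixelSize
    area <- counts[keep] * px^2
    data.frame(
        id = seq_along(keep),
        animal_id = mask@animalId,
        group = mask@groupLabel,
        plane_mm = mask@planeOffset,
        pixel_count = counts[keep],
        area_um2 = area,
        centroid_x_um = (sumC[keep] / counts[keep] + 0.5) * px,
        centroid_y_um = (sumR[keep] / counts[keep] + 0.5) * px,
        diameter_um = equivalentDiameter(area),
        row.names = NULL)
}

#' Circular-equivalent diameter
#'
#' Diameter of the circle whose area equals the given area:
#' d = 2 sqrt(A / pi). Monotone increasing in the area.
#'
#' @param area area(s) in um^2, each >= 0.
#' @return diameter(s) in um.
#' @examples
#' equivalentDiameter(269)  # ~18.5 um, printed as 19 um at integer precision
#' @export
equivalentDiameter <- function(area) {
    if (any(area < 0)) stop("'area' must be >= 0")
    2 * sqrt(area / pi)
}

#' Round a diameter to integer micrometres
#'
#' Round-half-up convention used for reported integer diameters and integer
#' fold changes.
#'
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

#' Per-plane hemorrhage summary
#'
#' @param bleeds a bleed table (see \code{\link{extractBleeds}}); all rows
#'   must share one coronal plane.
#' @param planeOffset optional plane (mm); defaults to the table's plane.
#' @return list with \code{plane_mm}, \code{n_bleeds}, \code{total_area_um2}
#'   (the exact sum of per-bleed areas).
#' @export
summarizePlane <- function(bleeds, planeOffset = NULL) {
    planes <- unique(bleeds$plane_mm[!is.na(bleeds$plane_mm)])
    if (length(planes) > 1L)
        stop("bleeds span multiple coronal planes: ",
             paste(planes, collapse = ", "))
    if (is.null(planeOffset))
        planeOffset <- if (length(planes)) planes else NA_real_
    else if (length(planes) && !isTRUE(all.equal(planes, planeOffset)))
        stop("bleed table plane does not match 'planeOffset'")
    list(plane_mm = planeOffset, n_bleeds = nrow(bleeds),
         total_area_um2 = sum(bleeds$area_um2))
}

#' Size-frequency histogram of microbleed areas
#'
#' Uniform-width bins anchored at 0, half-open on the right
#' ([0, w), [w, 2w), ...), so a bleed of exactly 500 um^2 falls in the
#' second bin at the default 500 um^2 width.
#'
#' @param bleeds a bleed table.
#' @param binWidth bin width in um^2 (> 0, default 500).
#' @param nBins optional number of bins; defaults to the smallest number
#'   covering the largest bleed (1 for an empty table).
#' @return data.frame with columns bin_lo_um2, bin_hi_um2, count;
#'   counts sum to the number of bleeds.
#' @export
sizeHistogram <- function(bleeds, binWidth = 500, nBins = NULL) {
    if (binWidth <= 0) stop("'binWidth' must be > 0")
    a <- bleeds$area_um2
    if (is.null(nBins))
        nBins <- if (length(a)) max(floor(max(a) / binWidth) + 1, 1) else 1L
    bin <- floor(a / binWidth) + 1L
    counts <- tabulate(bin, nbins = nBins)
    out <- data.frame(
        bin_lo_um2 = (seq_len(nBins) - 1) * binWidth,
        bin_hi_um2 = seq_len(nBins) * binWidth,
        count = counts)
    attr(out, "group") <- if (length(unique(bleeds$group)) == 1L)
        unique(bleeds$group) else NA_character_
    out
}

#' Spatial bleed map with hemispheres superimposed
#'
#' Pools bleeds of one group at one coronal plane and folds the two
#' hemispheres onto one side by reflecting centroids across the vertical
#' midline: x' = midline + |x - midline|. Mirror-image bleeds coincide after
#' folding. Entries are sorted by area, largest first, for stable rendering.
#'
#' @param bleeds a bleed table (one group, one plane).
#' @param midlineX the midline x coordinate in um.
#' @param planeOffset optional plane check, as in
#'   \code{\link{summarizePlane}}.
#' @return data.frame with columns plane_mm, x_um, y_um, area_um2, ordered
#'   by decreasing area.
#' @export
buildBleedMap <- function(bleeds, midlineX, planeOffset = NULL) {
    summarizePlane(bleeds, planeOffset)   # validates the single-plane premise
    if (!nrow(bleeds))
        return(data.frame(plane_mm = numeric(), x_um = numeric(),
                          y_um = numeric(), area_um2 = numeric()))
    out <- data.frame(
        plane_mm = bleeds$plane_mm,
        x_um = midlineX + abs(bleeds$centroid_x_um - midlineX),
        y_um = bleeds$centroid_y_um,
        area_um2 = bleeds$area_um2)
    out[order(-out$area_um2), , drop = FALSE]
}
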
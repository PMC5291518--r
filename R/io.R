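# File interfaces: TIFF/PNG section images, PNG masks, CSV sample/bleed
# tables, JSON boundary descriptions.

#' Read a section image from TIFF or PNG
#'
#' @param path file path ending in .tif, .tiff or .png.
#' @param pixelSize um per pixel calibration to attach.
#' @param planeOffset,animalId,groupLabel metadata to attach.
#' @return a \linkS4class{SectionImage} with 8-bit intensities (0-255).
#' @export
readSectionImage <- function(path, pixelSize = 2, planeOffset = NA_real_,
                             animalId = NA_character_,
                             groupLabel = NA_character_) {
    ext <- tolower(tools::file_ext(path))
    raw <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported image format: .", ext))
    if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
    if (dim(raw)[3] == 4L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
    SectionImage(raw * 255, pixelSize = pixelSize,
                 planeOffset = planeOffset, animalId = animalId,
                 groupLabel = groupLabel)
}

#' Write a section image as TIFF or PNG
#'
#' @param image a \linkS4class{SectionImage}.
#' @param path output path (.tif/.tiff or .png).
#' @return the path, invisibly.
#' @export
writeSectionImage <- function(image, path) {
    stopifnot(is(image, "SectionImage"))
    dat <- image@pixels / 255
    if (dim(dat)[3] == 1L) dat <- dat[, , 1]
    ext <- tolower(tools::file_ext(path))
    switch(ext,
        png = png::writePNG(dat, path),
        tif = ,
        tiff = tiff::writeTIFF(dat, path, bits.per.sample = 8L),
        stop("unsupported image format: .", ext))
    invisible(path)
}

#' Write a blood mask as a 0/255 single-channel PNG
#'
#' @param mask a \linkS4class{BloodMask} or logical matrix.
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
    m <- if (is(mask, "BloodMask")) mask@mask else mask
    png::writePNG(m * 1, path)
    invisible(path)
}

#' Read a blood mask from a 0/255 PNG
#'
#' @param path .png path.
#' @param pixelSize,planeOffset,animalId,groupLabel calibration and metadata
#'   to attach.
#' @return a \linkS4class{BloodMask}.
#' @export
readMask <- function(path, pixelSize = 2, planeOffset = NA_real_,
                     animalId = NA_character_, groupLabel = NA_character_) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    new("BloodMask", mask = raw > 0.5, pixelSize = pixelSize,
        planeOffset = planeOffset, animalId = animalId,
        groupLabel = groupLabel)
}

#' Read or write training samples as CSV
#'
#' The CSV carries columns \code{g}, \code{b} (intensities in [0, 255]) and
#' \code{label} (\code{blood} / \code{non-blood}).
#'
#' @param path CSV path.
#' @return \code{readTrainingSamples} a \linkS4class{PixelSampleSet}.
#' @export
readTrainingSamples <- function(path) {
    tab <- utils::read.csv(path)
    if (!all(c("g", "b", "label") %in% names(tab)))
        stop("training sample CSV needs columns g, b, label")
    new("PixelSampleSet",
        features = cbind(g = tab$g, b = tab$b),
        labels = factor(tab$label, levels = c("blood", "non-blood")))
}

#' @rdname readTrainingSamples
#' @param samples a \linkS4class{PixelSampleSet}.
#' @export
writeTrainingSamples <- function(samples, path) {
    stopifnot(is(samples, "PixelSampleSet"))
    utils::write.csv(
        data.frame(g = samples@features[, 1], b = samples@features[, 2],
                   label = as.character(samples@labels)),
        path, row.names = FALSE)
    invisible(path)
}

#' Read or write a linear boundary as JSON
#'
#' @param path JSON path.
#' @return \code{readBoundary} a \linkS4class{LinearBoundary}.
#' @export
readBoundary <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("LinearBoundary", w = as.numeric(j$w), b = as.numeric(j$b),
        margin = as.numeric(j$margin),
        trainingError = as.numeric(j$training_error),
        mode = if (is.null(j$mode)) "hard" else j$mode)
}

#' @rdname readBoundary
#' @param boundary a \linkS4class{LinearBoundary}.
#' @export
writeBoundary <- function(boundary, path) {
    stopifnot(is(boundary, "LinearBoundary"))
    jsonlite::write_json(
        list(w = boundary@w, b = boundary@b, margin = boundary@margin,
             training_error = boundary@trainingError, mode = boundary@mode),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write a synthetic section to disk with its ground truth
#'
#' Writes the image (PNG), the truth mask (0/255 PNG), the ground-truth
#' bleed table (CSV: id, centroid x/y in px and um, area in um^2) and a JSON
#' sidecar holding the configuration and seed.
#'
#' @param section a \linkS4class{SyntheticSection}.
#' @param dir output directory (created if missing).
#' @param stem file name stem.
#' @return the four paths, invisibly.
#' @export
writeSyntheticSection <- function(section, dir, stem = "section") {
    stopifnot(is(section, "SyntheticSection"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    px <- section@image@pixelSize
    paths <- file.path(dir, paste0(stem, c(".png", "_mask.png",
                                           "_truth.csv", "_config.json")))
    writeSectionImage(section@image, paths[1])
    writeMask(section@bloodTruth, paths[2])
    tr <- section@bleedTruth
    utils::write.csv(data.frame(
        id = tr$id,
        centroid_x_px = tr$centroid_x_um / px,
        centroid_y_px = tr$centroid_y_um / px,
        area_um2 = tr$area_um2), paths[3], row.names = FALSE)
    cfg <- section@config
    cfgList <- if (is(cfg, "SceneConfig")) {
        sn <- slotNames(cfg)
        stats::setNames(lapply(sn, function(s) slot(cfg, s)), sn)
    } else cfg
    jsonlite::write_json(cfgList, paths[4], auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    invisible(paths)
}

#' Write a bleed table as CSV
#'
#' Columns: animal_id, group, plane_mm, centroid_x_um, centroid_y_um,
#' area_um2, diameter_um.
#'
#' @param bleeds a bleed table from \code{\link{extractBleeds}}.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeBleedTable <- function(bleeds, path) {
    utils::write.csv(
        bleeds[, c("animal_id", "group", "plane_mm", "centroid_x_um",
                   "centroid_y_um", "area_um2", "diameter_um")],
        path, row.names = FALSE)
    invisible(path)
}
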
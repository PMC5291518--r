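# Synthetic histology generator: calibrated section images with full ground
# truth (painted blood mask, per-bleed records, known label fractions), so the
# detector, morphometry and ROI stages can be verified without tissue images.

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    force(expr)
}

#' Build a synthetic scene configuration
#'
#' Returns group-specific default parameters for the synthetic histology
#' generator. The defaults encode the statistical structure the analysis
#' assumes: every group carries small microbleeds (a uniform component below
#' 500 um^2), only the injured vaginal-delivery group (PS-VD) carries an
#' additional heavy large-bleed component, small bleeds are twice as frequent
#' in PS-VD as in the other groups, and placement is biased toward a
#' periventricular anchor. Group mean bleed areas under the defaults are
#' 269 um^2 (CTR-VD, mLPS-VD), 3097 um^2 (PS-VD mixture) and 340 um^2
#' (PS-AD).
#'
#' @param groupLabel one of \code{"CTR-VD"}, \code{"mLPS-VD"},
#'   \code{"PS-VD"}, \code{"PS-AD"}.
#' @param imageSize integer(2), image height and width in pixels.
#' @param pixelSize um per pixel (> 0).
#' @param planeOffset coronal plane, mm caudal to the rostral tip of the
#'   lateral ventricles.
#' @param nBleedsMean Poisson mean of the number of bleeds per section;
#'   defaults to 1 (10/3 for PS-VD).
#' @param bleedAreaDist,tissueColor,bloodColor,spatialBias optional lists
#'   overriding individual components of the group defaults (see
#'   \linkS4class{SceneConfig}).
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   configuration.
#' @return a validated \linkS4class{SceneConfig}.
#' @examples
#' cfg <- sceneConfig("PS-VD", seed = 1)
#' meanBleedArea(cfg)
#' @export
sceneConfig <- function(groupLabel = c("CTR-VD", "mLPS-VD", "PS-VD", "PS-AD"),
                        imageSize = c(512L, 512L), pixelSize = 2,
                        planeOffset = 2.5, nBleedsMean = NULL,
                        bleedAreaDist = list(), tissueColor = list(),
                        bloodColor = list(), spatialBias = list(),
                        seed = 1L) {
    groupLabel <- match.arg(groupLabel)
    # Small component Uniform(38, 500) has mean 269 um^2; the PS-AD small
    # component Uniform(180, 500) has mean 340 um^2. The PS-VD mixture puts
    # weight 0.4 on a Gamma(shape 4, mean 7339) large component so that
    # 0.6 * 269 + 0.4 * 7339 = 3097 um^2.
    area <- switch(groupLabel,
        "PS-VD" = list(smallMin = 38, smallMax = 500, largeWeight = 0.4,
                       largeMean = 7339, largeShape = 4),
        "PS-AD" = list(smallMin = 180, smallMax = 500, largeWeight = 0,
                       largeMean = 7339, largeShape = 4),
        list(smallMin = 38, smallMax = 500, largeWeight = 0,
             largeMean = 7339, largeShape = 4))
    area[names(bleedAreaDist)] <- bleedAreaDist
    if (is.null(nBleedsMean))
        nBleedsMean <- if (groupLabel == "PS-VD") 10 / 3 else 1
    tis <- list(mean = c(230, 185, 195), sd = 8)
    blo <- list(mean = c(150, 45, 50), sd = 8)
    tis[names(tissueColor)] <- tissueColor
    blo[names(bloodColor)] <- bloodColor
    sp <- list(anchor = c(0.45, 0.35), sd = c(0.2, 0.2))
    sp[names(spatialBias)] <- spatialBias
    new("SceneConfig", groupLabel = groupLabel,
        imageSize = as.integer(imageSize), pixelSize = as.numeric(pixelSize),
        planeOffset = as.numeric(planeOffset),
        nBleedsMean = as.numeric(nBleedsMean), bleedAreaDist = area,
        tissueColor = tis, bloodColor = blo, spatialBias = sp,
        seed = as.integer(seed))
}

#' Mean bleed area implied by a scene configuration
#'
#' The mixture mean of the configured bleed-area distribution, in um^2.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return numeric(1), um^2.
#' @export
meanBleedArea <- function(config) {
    d <- config@bleedAreaDist
    (1 - d$largeWeight) * (d$smallMin + d$smallMax) / 2 +
        d$largeWeight * d$largeMean
}

# Pixels of a disc of radius r (pixel units) centred at continuous pixel
# coordinates (cy, cx); pixel i (1-based) has centre i - 0.5.
discPixels <- function(cy, cx, r, H, W) {
    i0 <- max(1L, floor(cy - r)); i1 <- min(H, ceiling(cy + r + 1))
    j0 <- max(1L, floor(cx - r)); j1 <- min(W, ceiling(cx + r + 1))
    ii <- seq.int(i0, i1); jj <- seq.int(j0, j1)
    dy <- (ii - 0.5) - cy
    dx <- (jj - 0.5) - cx
    inside <- outer(dy^2, dx^2, "+") <= r^2
    w <- which(inside, arr.ind = TRUE)
    cbind(row = ii[w[, 1]], col = jj[w[, 2]])
}

# Randomly dilate a pixel set: each outside 4-neighbour of the set is added
# with probability p. Keeps every added pixel 8- (indeed 4-) connected.
dilatePixels <- function(px, p, H, W) {
    if (nrow(px) == 0L || p <= 0) return(px)
    nb <- rbind(
        cbind(px[, 1] - 1L, px[, 2]), cbind(px[, 1] + 1L, px[, 2]),
        cbind(px[, 1], px[, 2] - 1L), cbind(px[, 1], px[, 2] + 1L))
    nb <- nb[nb[, 1] >= 1L & nb[, 1] <= H & nb[, 2] >= 1L & nb[, 2] <= W, ,
             drop = FALSE]
    key <- nb[, 1] + (nb[, 2] - 1) * H
    have <- px[, 1] + (px[, 2] - 1) * H
    cand <- unique(key[!key %in% have])
    keep <- cand[stats::runif(length(cand)) < p]
    if (length(keep))
        px <- rbind(px, cbind(row = (keep - 1) %% H + 1,
                              col = (keep - 1) %/% H + 1))
    px
}

#' Generate a synthetic stained section with ground truth
#'
#' Paints a tissue-coloured background, places bleeds as rasterized discs
#' (perturbed by random boundary dilation, so each bleed is one 8-connected
#' component) with target areas drawn from the configured size mixture and
#' centres drawn from the periventricular placement density, then samples
#' every pixel's RGB value from the Gaussian colour cluster of its truth
#' class. Bleeds never overlap or touch, so the painted mask decomposes
#' exactly into the ground-truth components.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param nBleeds optional integer overriding the Poisson draw of the bleed
#'   count (used to request an exact number of bleeds).
#' @return a \linkS4class{SyntheticSection}; its painted-truth area equals
#'   the sum of the ground-truth bleed areas exactly.
#' @examples
#' sec <- generateSection(sceneConfig("CTR-VD", imageSize = c(96L, 96L),
#'                                    seed = 3))
#' nrow(bleedTruth(sec))
#' @export
generateSection <- function(config, nBleeds = NULL) {
    validObject(config)
    withSeed(config@seed, {
        H <- config@imageSize[1]; W <- config@imageSize[2]
        px <- config@pixelSize
        n <- if (is.null(nBleeds)) stats::rpois(1, config@nBleedsMean)
             else as.integer(nBleeds)
        d <- config@bleedAreaDist
        targets <- numeric(0)
        if (n > 0) {
            large <- stats::runif(n) < d$largeWeight
            targets <- ifelse(large,
                stats::rgamma(n, shape = d$largeShape,
                              scale = d$largeMean / d$largeShape),
                stats::runif(n, d$smallMin, d$smallMax))
        }
        truth <- matrix(FALSE, H, W)
        anchor <- config@spatialBias$anchor * c(H, W)
        spsd <- config@spatialBias$sd * c(H, W)
        rows <- vector("list", n)
        for (k in seq_len(n)) {
            r <- sqrt(targets[k] / pi) / px
            placed <- FALSE
            if (2 + r >= H - 2 - r || 2 + r >= W - 2 - r)
                stop(sprintf(
                    "could not place bleed %d (target area %.1f um^2) in a %d x %d image",
                    k, targets[k], H, W))
            for (try in seq_len(1000L)) {
                if (try <= 300L) {
                    cy <- stats::rnorm(1, anchor[1], spsd[1])
                    cx <- stats::rnorm(1, anchor[2], spsd[2])
                } else {
                    # crowded scene: fall back to uniform placement over the
                    # in-bounds region so the requested bleeds still fit
                    cy <- stats::runif(1, 2 + r, H - 2 - r)
                    cx <- stats::runif(1, 2 + r, W - 2 - r)
                }
                if (cy - r < 2 || cy + r > H - 2 || cx - r < 2 ||
                    cx + r > W - 2) next
                pxs <- discPixels(cy, cx, r, H, W)
                if (nrow(pxs) == 0L)  # sub-pixel bleed: paint its centre pixel
                    pxs <- cbind(row = ceiling(cy), col = ceiling(cx))
                pxs <- dilatePixels(pxs, 0.15, H, W)
                # require 1-px clearance from previously painted bleeds so
                # ground-truth components never merge under 8-connectivity
                halo <- cbind(rep(pxs[, 1], 9L) + rep(-1:1, each = nrow(pxs) * 3L),
                              rep(pxs[, 2], 9L) + rep(rep(-1:1, each = nrow(pxs)), 3L))
                halo <- halo[halo[, 1] >= 1L & halo[, 1] <= H &
                             halo[, 2] >= 1L & halo[, 2] <= W, , drop = FALSE]
                if (any(truth[halo])) next
                truth[pxs] <- TRUE
                rows[[k]] <- data.frame(
                    id = k,
                    centroid_x_um = (mean(pxs[, 2]) - 0.5) * px,
                    centroid_y_um = (mean(pxs[, 1]) - 0.5) * px,
                    pixel_count = nrow(pxs),
                    area_um2 = nrow(pxs) * px^2,
                    target_area_um2 = targets[k])
                placed <- TRUE
                break
            }
            if (!placed)
                stop(sprintf(
                    "could not place bleed %d (target area %.1f um^2) in a %d x %d image",
                    k, targets[k], H, W))
        }
        bleeds <- if (n > 0) do.call(rbind, rows) else
            data.frame(id = integer(), centroid_x_um = numeric(),
                       centroid_y_um = numeric(), pixel_count = integer(),
                       area_um2 = numeric(), target_area_um2 = numeric())
        pixels <- array(0, dim = c(H, W, 3L))
        for (ch in 1:3) {
            plane <- matrix(stats::rnorm(H * W, config@tissueColor$mean[ch],
                                         config@tissueColor$sd), H, W)
            nb <- sum(truth)
            if (nb)
                plane[truth] <- stats::rnorm(nb, config@bloodColor$mean[ch],
                                             config@bloodColor$sd)
            pixels[, , ch] <- pmin(pmax(plane, 0), 255)
        }
        img <- SectionImage(pixels, pixelSize = px,
                            planeOffset = config@planeOffset,
                            animalId = NA_character_,
                            groupLabel = config@groupLabel)
        new("SyntheticSection", image = img, bloodTruth = truth,
            bleedTruth = bleeds, labelFractionTruth = NA_real_,
            config = config)
    })
}

#' Sample labeled training pixels from a synthetic section
#'
#' Emulates hand-selection of blood-positive and blood-negative training
#' pixels: draws, without replacement, \code{nPos} truth-positive and
#' \code{nNeg} truth-negative pixel coordinates and records their
#' (green, blue) features.
#'
#' @param section a \linkS4class{SyntheticSection} (histology mode).
#' @param nPos,nNeg numbers of positive and negative samples.
#' @param seed integer RNG seed.
#' @return a \linkS4class{PixelSampleSet}.
#' @export
sampleTrainingPixels <- function(section, nPos, nNeg, seed = 1L) {
    stopifnot(is(section, "SyntheticSection"))
    truth <- section@bloodTruth
    pos <- which(truth); neg <- which(!truth)
    if (length(pos) < nPos)
        stop(sprintf(
            "insufficient blood-positive pixels: %d available, %d requested",
            length(pos), nPos))
    if (length(neg) < nNeg)
        stop(sprintf(
            "insufficient blood-negative pixels: %d available, %d requested",
            length(neg), nNeg))
    withSeed(seed, {
        ip <- if (nPos > 0) sample(pos, nPos) else integer()
        iq <- if (nNeg > 0) sample(neg, nNeg) else integer()
        g <- section@image@pixels[, , 2]
        b <- section@image@pixels[, , 3]
        feats <- cbind(g = c(g[ip], g[iq]), b = c(b[ip], b[iq]))
        labs <- factor(rep(c("blood", "non-blood"), c(nPos, nNeg)),
                       levels = c("blood", "non-blood"))
        new("PixelSampleSet", features = feats, labels = labs)
    })
}

#' Generate a fluorescence-like image with a known positive fraction
#'
#' Produces a single-channel image in which an exact number of pixels --
#' \code{round(positiveFraction * npixels)} -- carries intensity
#' \code{positiveLevel} and the rest carries \code{backgroundLevel}, plus
#' optional clipped Gaussian noise. The realized fraction is recorded as the
#' ground truth for the 2x-background ROI rule.
#'
#' @param backgroundLevel,positiveLevel intensities in [0, 255].
#' @param positiveFraction fraction of positive pixels in [0, 1].
#' @param imageSize integer(2), height and width in pixels.
#' @param seed integer RNG seed.
#' @param noiseSd standard deviation of additive Gaussian noise (default 0:
#'   noise free).
#' @param pixelSize um per pixel.
#' @return a \linkS4class{SyntheticSection} whose \code{bloodTruth} slot
#'   holds the positive-pixel mask and whose \code{labelFractionTruth} is
#'   the exact positive fraction.
#' @examples
#' fl <- generateFluorescenceImage(40, 0.25, 200,
#'                                 imageSize = c(50L, 50L), seed = 2)
#' labelFractionTruth(fl)
#' @export
generateFluorescenceImage <- function(backgroundLevel, positiveFraction,
                                      positiveLevel,
                                      imageSize = c(256L, 256L), seed = 1L,
                                      noiseSd = 0, pixelSize = 2) {
    if (positiveFraction < 0 || positiveFraction > 1)
        stop("'positiveFraction' must lie in [0, 1]")
    if (backgroundLevel < 0 || backgroundLevel > 255 ||
        positiveLevel < 0 || positiveLevel > 255)
        stop("intensity levels must lie in [0, 255]")
    H <- as.integer(imageSize[1]); W <- as.integer(imageSize[2])
    withSeed(seed, {
        npix <- H * W
        nPos <- round(positiveFraction * npix)
        mask <- matrix(FALSE, H, W)
        if (nPos > 0) mask[sample.int(npix, nPos)] <- TRUE
        plane <- matrix(backgroundLevel, H, W)
        plane[mask] <- positiveLevel
        if (noiseSd > 0)
            plane <- pmin(pmax(plane + stats::rnorm(npix, 0, noiseSd), 0), 255)
        img <- SectionImage(array(plane, dim = c(H, W, 1L)),
                            pixelSize = pixelSize)
        new("SyntheticSection", image = img, bloodTruth = mask,
            bleedTruth = data.frame(), labelFractionTruth = nPos / npix,
            config = list(backgroundLevel = backgroundLevel,
                          positiveLevel = positiveLevel, noiseSd = noiseSd,
                          seed = as.integer(seed)))
    })
}
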
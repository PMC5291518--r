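# Blood-pixel detection: hard-margin linear classification in the
# (green, blue) channel plane, mirroring the zero-training-error premise of
# the original analysis. The maximum-margin separator of two linearly
# separable point sets in the plane is the perpendicular bisector of the
# closest pair of points between their convex hulls, which is computed here
# exactly from hull geometry.

#' Extract (green, blue) pixel features
#'
#' Isolates the green and blue channels of an RGB section; the red channel is
#' discarded and never influences classification.
#'
#' @param image a 3-channel \linkS4class{SectionImage}.
#' @return numeric array H x W x 2, feature planes \code{g} then \code{b}.
#' @export
extractFeatures <- function(image) {
    stopifnot(is(image, "SectionImage"))
    if (dim(image@pixels)[3] != 3L)
        stop("feature extraction requires a 3-channel RGB image")
    feats <- image@pixels[, , 2:3, drop = FALSE]
    dimnames(feats) <- list(NULL, NULL, c("g", "b"))
    feats
}

# distance from point p to segment [a, b], with the closest point
pointSegDist <- function(p, a, b) {
    d <- b - a
    l2 <- sum(d^2)
    t <- if (l2 == 0) 0 else min(max(sum((p - a) * d) / l2, 0), 1)
    q <- a + t * d
    list(dist = sqrt(sum((p - q)^2)), point = q)
}

segsIntersect <- function(p1, p2, q1, q2) {
    orient <- function(a, b, c)
        sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    onSeg <- function(a, b, c)
        min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
        min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
    o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
    o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
    if (o1 != o2 && o3 != o4) return(TRUE)
    (o1 == 0 && onSeg(p1, p2, q1)) || (o2 == 0 && onSeg(p1, p2, q2)) ||
        (o3 == 0 && onSeg(q1, q2, p1)) || (o4 == 0 && onSeg(q1, q2, p2))
}

# min distance between segments [p1,p2] and [q1,q2] with the closest pair
segSegDist <- function(p1, p2, q1, q2) {
    if (segsIntersect(p1, p2, q1, q2))
        return(list(dist = 0, p = p1, q = p1))
    best <- NULL
    for (cand in list(
        c(pointSegDist(p1, q1, q2), list(p = p1)),
        c(pointSegDist(p2, q1, q2), list(p = p2)))) {
        if (is.null(best) || cand$dist < best$dist)
            best <- list(dist = cand$dist, p = cand$p, q = cand$point)
    }
    for (q in list(q1, q2)) {
        cand <- pointSegDist(q, p1, p2)
        if (cand$dist < best$dist)
            best <- list(dist = cand$dist, p = cand$point, q = q)
    }
    best
}

# strict interior test for a convex polygon given as vertex matrix (k x 2)
insideConvex <- function(p, verts) {
    k <- nrow(verts)
    if (k < 3L) return(FALSE)
    s <- vapply(seq_len(k), function(i) {
        a <- verts[i, ]; b <- verts[if (i == k) 1L else i + 1L, ]
        (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    }, numeric(1))
    all(s > 0) || all(s < 0)
}

# closest pair of points between the convex hulls of two point sets, or
# dist 0 if the hulls intersect / one contains the other
hullClosestPair <- function(P, Q) {
    hp <- P[grDevices::chull(P), , drop = FALSE]
    hq <- Q[grDevices::chull(Q), , drop = FALSE]
    edges <- function(h) {
        k <- nrow(h)
        lapply(seq_len(k), function(i)
            list(a = h[i, ], b = h[if (i == k) 1L else i + 1L, ]))
    }
    if (insideConvex(hp[1, ], hq) || insideConvex(hq[1, ], hp))
        return(list(dist = 0))
    best <- NULL
    for (ep in edges(hp)) for (eq in edges(hq)) {
        cand <- segSegDist(ep$a, ep$b, eq$a, eq$b)
        if (is.null(best) || cand$dist < best$dist) best <- cand
        if (best$dist == 0) return(best)
    }
    best
}

#' Train the blood/non-blood linear classifier
#'
#' Fits the maximum-margin linear separator of the blood and non-blood
#' samples in the (green, blue) plane. In the default hard-margin mode the
#' samples must be perfectly linearly separable -- the premise under which
#' training data show no classification error -- and the fit is exact: the
#' boundary is the perpendicular bisector of the closest pair of points
#' between the two class convex hulls, and the geometric margin is half
#' their distance. Non-separable input raises an error rather than silently
#' degrading.
#'
#' With \code{mode = "soft"} an explicit soft-margin fallback
#' (\code{\link[e1071]{svm}}, linear kernel, unscaled features) is fitted
#' instead; its training error may exceed zero.
#'
#' @param samples a \linkS4class{PixelSampleSet} with at least one sample of
#'   each class.
#' @param mode \code{"hard"} (default) or \code{"soft"}.
#' @param cost soft-margin cost parameter (ignored in hard mode).
#' @return a \linkS4class{LinearBoundary}; blood pixels satisfy
#'   \code{w . (g, b) + b > 0}, and points exactly on the boundary classify
#'   as non-blood.
#' @examples
#' s <- new("PixelSampleSet",
#'          features = rbind(c(10, 10), c(200, 200)),
#'          labels = factor(c("blood", "non-blood"),
#'                          levels = c("blood", "non-blood")))
#' boundaryMargin(trainClassifier(s))  # half the point distance
#' @export
trainClassifier <- function(samples, mode = c("hard", "soft"), cost = 1) {
    mode <- match.arg(mode)
    validObject(samples)
    X <- samples@features
    y <- samples@labels
    if (!all(c("blood", "non-blood") %in% y))
        stop("training requires at least one sample of each class")
    P <- X[y == "blood", , drop = FALSE]
    Q <- X[y == "non-blood", , drop = FALSE]
    if (mode == "hard") {
        cp <- hullClosestPair(P, Q)
        if (cp$dist <= 1e-9)
            stop("training samples are not linearly separable; ",
                 "the hard-margin premise (zero classification error) is ",
                 "violated. Use mode = 'soft' to fit anyway.")
        wdir <- (cp$p - cp$q) / cp$dist     # unit normal, points toward blood
        mid <- (cp$p + cp$q) / 2
        w <- as.numeric(wdir)
        b <- -sum(wdir * mid)
        boundary <- new("LinearBoundary", w = w, b = b, margin = cp$dist / 2,
                        trainingError = 0, mode = "hard")
        scores <- as.numeric(X %*% w + b)
        err <- mean((scores > 0) != (y == "blood"))
        if (err > 0)
            stop("internal error: hard-margin fit misclassifies training data")
        boundary
    } else {
        fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                          scale = FALSE)
        w <- as.numeric(t(fit$coefs) %*% fit$SV)
        b <- -fit$rho
        # orient so that blood-side scores are positive
        med <- stats::median(sign(X[y == "blood", , drop = FALSE] %*% w + b))
        if (is.finite(med) && med < 0) {
            w <- -w; b <- -b
        }
        scores <- as.numeric(X %*% w + b)
        err <- mean((scores > 0) != (y == "blood"))
        new("LinearBoundary", w = w, b = b, margin = 1 / sqrt(sum(w^2)),
            trainingError = err, mode = "soft")
    }
}

#' Classify every pixel of a section
#'
#' Applies a trained \linkS4class{LinearBoundary} to all pixels of a
#' section: a pixel is blood-positive iff its (green, blue) features lie
#' strictly on the blood side of the boundary. Ties (score exactly 0)
#' classify as non-blood.
#'
#' @param image a 3-channel \linkS4class{SectionImage}.
#' @param boundary a \linkS4class{LinearBoundary}.
#' @return a \linkS4class{BloodMask} congruent with the image.
#' @export
classifyPixels <- function(image, boundary) {
    stopifnot(is(image, "SectionImage"), is(boundary, "LinearBoundary"))
    feats <- extractFeatures(image)
    score <- boundary@w[1] * feats[, , 1] + boundary@w[2] * feats[, , 2] +
        boundary@b
    new("BloodMask", mask = score > 0, pixelSize = image@pixelSize,
        planeOffset = image@planeOffset, animalId = image@animalId,
        groupLabel = image@groupLabel)
}

#' Total blood area of a mask
#'
#' @param mask a \linkS4class{BloodMask}.
#' @return numeric(1), blood-positive pixel count times the squared pixel
#'   size, in um^2.
#' @export
totalBloodArea <- function(mask) {
    stopifnot(is(mask, "BloodMask"))
    sum(mask@mask) * mask@pixelSize^2
}
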
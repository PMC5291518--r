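# Independent oracles and fixture builders. Each oracle is deliberately
# implemented by a different route than the package code it checks.

makeSampleSet <- function(features, labels) {
    new("PixelSampleSet",
        features = as.matrix(features),
        labels = factor(labels, levels = c("blood", "non-blood")))
}

# Brute-force maximum-margin oracle: scan separator directions on a dense
# angle grid, refine around the best with 1-d optimisation. For a unit
# direction u, the best achievable geometric margin with blood on the
# positive side is (min_blood u.x - max_nonblood u.x) / 2.
bruteForceMargin <- function(features, labels, nAngles = 8192L) {
    P <- features[labels == "blood", , drop = FALSE]
    Q <- features[labels == "non-blood", , drop = FALSE]
    marginAt <- function(theta) {
        u <- c(cos(theta), sin(theta))
        (min(P %*% u) - max(Q %*% u)) / 2
    }
    thetas <- seq(0, 2 * pi, length.out = nAngles + 1L)[-1L]
    m <- vapply(thetas, marginAt, numeric(1))
    i <- which.max(m)
    lo <- thetas[max(i - 1L, 1L)]
    hi <- thetas[min(i + 1L, nAngles)]
    opt <- stats::optimize(marginAt, c(lo, hi), maximum = TRUE,
                           tol = 1e-12)
    max(opt$objective, m[i])
}

# Independent separability check: a high-cost soft-margin SVM (e1071)
# reaches zero training error iff the classes are linearly separable.
isSeparableSVM <- function(features, labels) {
    fit <- e1071::svm(x = features, y = labels, kernel = "linear",
                      cost = 1e8, scale = FALSE)
    all(stats::predict(fit, features) == labels)
}

# Brute-force 8-connected component labeling: per-pixel flood fill with an
# explicit stack (no recursion), scanning row-major (unlike the package's
# column-major pass), so only the partition is comparable, not raw labels.
floodFillLabels <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    lab <- matrix(0L, H, W)
    cur <- 0L
    for (i in seq_len(H)) for (j in seq_len(W)) {
        if (mask[i, j] && lab[i, j] == 0L) {
            cur <- cur + 1L
            stack <- list(c(i, j))
            lab[i, j] <- cur
            while (length(stack)) {
                p <- stack[[length(stack)]]
                stack[[length(stack)]] <- NULL
                for (di in -1:1) for (dj in -1:1) {
                    ni <- p[1] + di; nj <- p[2] + dj
                    if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
                        mask[ni, nj] && lab[ni, nj] == 0L) {
                        lab[ni, nj] <- cur
                        stack[[length(stack) + 1L]] <- c(ni, nj)
                    }
                }
            }
        }
    }
    lab
}

# TRUE iff two labelings induce the same partition of the TRUE pixels.
samePartition <- function(labA, labB) {
    idx <- which(labA > 0)
    if (!identical(which(labB > 0), idx)) return(FALSE)
    a <- labA[idx]; b <- labB[idx]
    !anyDuplicated(unique(cbind(a, b))[, 1]) &&
        !anyDuplicated(unique(cbind(a, b))[, 2])
}

# Small scene for fast unit tests: 128 x 128 px at 2 um/px, bleeds large
# enough (>= ~37 px) that training sets of up to ~70 positives can be drawn.
smallConfig <- function(group = "PS-VD", seed = 1L, ...) {
    sceneConfig(group, imageSize = c(128L, 128L), seed = seed,
                bleedAreaDist = list(smallMin = 150, largeMean = 2000), ...)
}

# Fisher-LSD pairwise t-test p (pooled MSE across all groups), the
# unadjusted post-hoc comparison Tukey HSD is guaranteed to dominate.
lsdP <- function(values, groups, a, b) {
    groups <- factor(groups)
    k <- nlevels(groups); N <- length(values)
    mse <- sum(tapply(values, groups,
                      function(x) sum((x - mean(x))^2))) / (N - k)
    na <- sum(groups == a); nb <- sum(groups == b)
    tstat <- (mean(values[groups == a]) - mean(values[groups == b])) /
        sqrt(mse * (1 / na + 1 / nb))
    2 * stats::pt(-abs(tstat), N - k)
}

# Manual one-way ANOVA F statistic (sums of squares written out directly).
manualF <- function(values, groups) {
    gm <- tapply(values, groups, mean)
    ns <- tapply(values, groups, length)
    ssb <- sum(ns * (gm - mean(values))^2)
    ssw <- sum((values - gm[groups])^2)
    k <- length(gm); N <- length(values)
    (ssb / (k - 1)) / (ssw / (N - k))
}

# Uniform random blood mask fixture.
randomMask <- function(H = 64L, W = 64L, p = 0.4, pixelSize = 2) {
    new("BloodMask", mask = matrix(runif(H * W) < p, H, W),
        pixelSize = pixelSize)
}
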
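# Hard-margin blood-pixel classifier: feature extraction, exact maximum
# margin, classification rule, calibrated areas.

test_that("feature extraction isolates the green and blue channels", {
    u <- array(rep(c(10, 20, 30), each = 4), dim = c(2, 2, 3))
    f <- extractFeatures(SectionImage(u))
    expect_true(all(f[, , "g"] == 20) && all(f[, , "b"] == 30))

    two <- array(c(0, 255, 0, 255, 0, 255), dim = c(1, 2, 3))
    f2 <- extractFeatures(SectionImage(two))
    expect_equal(as.numeric(f2[1, , ]), c(0, 255, 0, 255))

    sec <- generateSection(smallConfig(seed = 2L))
    img <- sectionImage(sec)
    f3 <- extractFeatures(img)
    expect_identical(f3[, , 1], imagePixels(img)[, , 2])
    expect_identical(f3[, , 2], imagePixels(img)[, , 3])

    expect_error(extractFeatures(SectionImage(matrix(0, 3, 3))), "3-channel")
})

test_that("two-point training gives the perpendicular bisector", {
    ss <- makeSampleSet(rbind(c(10, 10), c(200, 200)),
                        c("blood", "non-blood"))
    bd <- trainClassifier(ss)
    expect_equal(boundaryMargin(bd), sqrt(2 * 190^2) / 2, tolerance = 1e-12)
    expect_identical(trainingError(bd), 0)
    sc <- function(x) sum(boundaryWeights(bd) * x) + boundaryBias(bd)
    expect_gt(sc(c(10, 10)), 0)
    expect_lt(sc(c(200, 200)), 0)
})

test_that("coincident points with opposite labels are inseparable", {
    ss <- makeSampleSet(rbind(c(0, 0), c(0, 0)), c("blood", "non-blood"))
    expect_error(trainClassifier(ss), "not linearly separable")
})

test_that("single-class input is rejected", {
    ss <- makeSampleSet(rbind(c(1, 2), c(3, 4)), c("blood", "blood"))
    expect_error(trainClassifier(ss), "each class")
})

test_that("margin matches the brute-force maximum-margin oracle", {
    four <- makeSampleSet(rbind(c(10, 10), c(20, 10), c(100, 100),
                                c(110, 120)),
                          c("blood", "blood", "non-blood", "non-blood"))
    bd <- trainClassifier(four)
    oracle <- bruteForceMargin(sampleFeatures(four), sampleLabels(four))
    expect_equal(boundaryMargin(bd), oracle, tolerance = 1e-3)

    set.seed(20)
    for (rep in 1:25) {
        n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
        X <- rbind(matrix(rnorm(2 * n1, 40, 12), ncol = 2),
                   matrix(rnorm(2 * n2, 140, 12), ncol = 2))
        X <- pmin(pmax(X, 0), 255)
        y <- rep(c("blood", "non-blood"), c(n1, n2))
        if (!isSeparableSVM(X, factor(y, c("blood", "non-blood")))) next
        bd <- trainClassifier(makeSampleSet(X, y))
        oracle <- bruteForceMargin(X, factor(y, c("blood", "non-blood")))
        expect_identical(trainingError(bd), 0)
        # agreement to 3 significant figures (relative tolerance)
        expect_equal(boundaryMargin(bd), oracle, tolerance = 1e-3)
    }
})

test_that("hard-margin training reports zero error on every separable set", {
    for (seed in 1:10) {
        sec <- generateSection(smallConfig(seed = seed), nBleeds = 2L)
        ss <- sampleTrainingPixels(sec, 60, 60, seed = seed)
        expect_identical(trainingError(trainClassifier(ss)), 0)
    }
})

test_that("the soft-margin fallback handles inseparable data explicitly", {
    set.seed(9)
    X <- matrix(runif(80, 0, 255), ncol = 2)
    y <- rep(c("blood", "non-blood"), each = 20)
    ss <- makeSampleSet(X, y)
    expect_error(trainClassifier(ss), "not linearly separable")
    bd <- trainClassifier(ss, mode = "soft")
    expect_gte(trainingError(bd), 0)
    expect_true(bd@mode == "soft")
})

test_that("classification covers every pixel and ties fall to non-blood", {
    bd <- new("LinearBoundary", w = c(-1, -1), b = 200, margin = 1,
              trainingError = 0, mode = "hard")
    blood <- SectionImage(array(rep(c(0, 20, 30), each = 4),
                                dim = c(2, 2, 3)))
    expect_true(all(maskMatrix(classifyPixels(blood, bd))))
    tissue <- SectionImage(array(rep(c(0, 200, 220), each = 4),
                                 dim = c(2, 2, 3)))
    expect_false(any(maskMatrix(classifyPixels(tissue, bd))))
    # score exactly zero: g + b = 200
    tie <- SectionImage(array(rep(c(0, 100, 100), each = 4),
                              dim = c(2, 2, 3)))
    expect_false(any(maskMatrix(classifyPixels(tie, bd))))
})

test_that("the red channel never influences the mask", {
    sec <- generateSection(smallConfig(seed = 6L))
    ss <- sampleTrainingPixels(sec, 50, 50, seed = 1L)
    bd <- trainClassifier(ss)
    img <- sectionImage(sec)
    m1 <- maskMatrix(classifyPixels(img, bd))
    px <- imagePixels(img)
    px[, , 1] <- 255 - px[, , 1]
    m2 <- maskMatrix(classifyPixels(SectionImage(px,
        pixelSize = pixelSize(img)), bd))
    expect_identical(m1, m2)
})

test_that("classification agrees with ground truth on synthetic sections", {
    for (seed in 1:5) {
        sec <- generateSection(smallConfig(seed = seed), nBleeds = 3L)
        ss <- sampleTrainingPixels(sec, 60, 60, seed = seed)
        bd <- trainClassifier(ss)
        m <- maskMatrix(classifyPixels(sectionImage(sec), bd))
        agreement <- mean(m == maskMatrix(sec))
        expect_gte(agreement, 0.99)
    }
})

test_that("total blood area is count times squared pixel size", {
    m0 <- new("BloodMask", mask = matrix(FALSE, 5, 5), pixelSize = 2)
    expect_identical(totalBloodArea(m0), 0)
    mm <- matrix(FALSE, 20, 20); mm[1:10, 1:10] <- TRUE
    m1 <- new("BloodMask", mask = mm, pixelSize = 2)
    expect_identical(totalBloodArea(m1), 400)
    # scale behaviour: pixel size x k multiplies area by k^2 exactly
    for (k in c(0.5, 3, 7)) {
        mk <- new("BloodMask", mask = mm, pixelSize = 2 * k)
        expect_identical(totalBloodArea(mk), 400 * k^2)
    }
})
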
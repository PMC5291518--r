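# Microbleed morphometry: component labeling vs flood-fill oracle, area
# conservation, equivalent diameters, plane summaries, histograms, maps.

blockMask <- function() {
    mm <- matrix(FALSE, 20, 20)
    mm[1:10, 1:10] <- TRUE
    new("BloodMask", mask = mm, pixelSize = 2, planeOffset = 2.5,
        animalId = "a1", groupLabel = "PS-VD")
}

test_that("an empty mask yields an empty bleed table", {
    m <- new("BloodMask", mask = matrix(FALSE, 8, 8), pixelSize = 2)
    expect_identical(nrow(extractBleeds(m)), 0L)
})

test_that("a solid block is one bleed with exact area and centroid", {
    b <- extractBleeds(blockMask())
    expect_identical(nrow(b), 1L)
    expect_identical(b$pixel_count, 100L)
    expect_identical(b$area_um2, 400)
    # block spans 0..20 um on both axes; centre at 10 um
    expect_equal(b$centroid_x_um, 10)
    expect_equal(b$centroid_y_um, 10)
    expect_equal(b$diameter_um, equivalentDiameter(400))
})

test_that("component labeling matches the flood-fill oracle", {
    set.seed(31)
    for (rep in 1:150) {
        m <- randomMask(32L, 32L, p = runif(1, 0.2, 0.6))
        lab <- microbleedR:::label_components_8(maskMatrix(m))
        expect_true(samePartition(lab, floodFillLabels(maskMatrix(m))))
    }
})

test_that("summed bleed areas equal the total mask area at minPixels = 1", {
    set.seed(32)
    for (rep in 1:25) {
        m <- randomMask(48L, 48L, p = runif(1, 0.1, 0.7))
        b <- extractBleeds(m, minPixels = 1)
        expect_identical(sum(b$area_um2), totalBloodArea(m))
        expect_identical(sum(b$pixel_count), sum(maskMatrix(m)))
    }
})

test_that("components below minPixels are discarded", {
    mm <- matrix(FALSE, 10, 10)
    mm[1, 1] <- TRUE                 # singleton speckle
    mm[5:6, 5:6] <- TRUE             # 4-px bleed
    m <- new("BloodMask", mask = mm, pixelSize = 2)
    b <- extractBleeds(m, minPixels = 2)
    expect_identical(nrow(b), 1L)
    expect_identical(b$pixel_count, 4L)
    expect_identical(nrow(extractBleeds(m, minPixels = 1)), 2L)
})

test_that("bleed ids are stable across repeated extraction", {
    set.seed(33)
    m <- randomMask(40L, 40L, 0.45)
    expect_identical(extractBleeds(m), extractBleeds(m))
})

test_that("equivalent diameter reproduces the closed form and printed values", {
    expect_identical(equivalentDiameter(0), 0)
    expect_equal(equivalentDiameter(pi), 2)
    # printed group means -> printed integer diameters
    d <- equivalentDiameter(c(269, 3097, 340))
    expect_equal(d, c(18.50679, 62.79509, 20.80628), tolerance = 1e-6)
    expect_identical(roundHalfUp(d), c(19, 63, 21))
    expect_error(equivalentDiameter(-1), ">= 0")
    # monotone and exactly invertible: A = pi (d/2)^2
    a <- sort(runif(50, 0, 5000))
    d <- equivalentDiameter(a)
    expect_false(is.unsorted(d))
    expect_equal(pi * (d / 2)^2, a, tolerance = 1e-12)
})

test_that("plane summaries total the bleed areas and reject mixed planes", {
    expect_identical(summarizePlane(emptyTable <- extractBleeds(
        new("BloodMask", mask = matrix(FALSE, 4, 4),
            pixelSize = 2)))$total_area_um2, 0)
    b <- data.frame(area_um2 = c(100, 300), plane_mm = c(2.5, 2.5))
    s <- summarizePlane(b)
    expect_identical(s$total_area_um2, 400)
    expect_identical(s$plane_mm, 2.5)
    mixed <- data.frame(area_um2 = c(1, 2), plane_mm = c(2.0, 2.5))
    expect_error(summarizePlane(mixed), "multiple coronal planes")
})

test_that("plane summary equals mask total on synthetic sections", {
    sec <- generateSection(smallConfig(seed = 41L), nBleeds = 3L)
    m <- new("BloodMask", mask = maskMatrix(sec),
             pixelSize = pixelSize(sectionImage(sec)), planeOffset = 2.5)
    b <- extractBleeds(m, minPixels = 1)
    expect_identical(summarizePlane(b)$total_area_um2, totalBloodArea(m))
})

test_that("size histograms use half-open uniform bins anchored at zero", {
    b <- data.frame(area_um2 = c(100, 499, 500), plane_mm = 2.5,
                    group = "PS-VD")
    h <- sizeHistogram(b, binWidth = 500)
    expect_identical(h$count, c(2L, 1L))
    expect_identical(h$bin_lo_um2, c(0, 500))
    empty <- sizeHistogram(data.frame(area_um2 = numeric(),
                                      group = character()), 500)
    expect_identical(sum(empty$count), 0L)

    set.seed(44)
    areas <- rgamma(1000, 2, scale = 800)
    bb <- data.frame(area_um2 = areas, group = "PS-VD")
    h2 <- sizeHistogram(bb, binWidth = 500)
    # independent tally oracle
    oracle <- vapply(seq_len(nrow(h2)), function(i)
        sum(areas >= h2$bin_lo_um2[i] & areas < h2$bin_hi_um2[i]),
        integer(1))
    expect_identical(h2$count, oracle)
    expect_identical(sum(h2$count), 1000L)
})

test_that("bleed maps fold hemispheres across the midline", {
    b <- data.frame(plane_mm = 2.5,
                    centroid_x_um = c(200, 800),   # mirror pair about 500
                    centroid_y_um = c(120, 120),
                    area_um2 = c(50, 60),
                    group = "PS-VD")
    m <- buildBleedMap(b, midlineX = 500)
    expect_identical(m$x_um, c(800, 800))
    expect_identical(m$area_um2, c(60, 50))   # sorted by area, descending
    single <- buildBleedMap(b[1, ], midlineX = 500)
    expect_identical(single$x_um, 800)
    none <- buildBleedMap(b[0, ], midlineX = 500)
    expect_identical(nrow(none), 0L)
})
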
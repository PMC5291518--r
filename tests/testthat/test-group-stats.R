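# Group statistics: mean +/- SE, one-way ANOVA, Tukey HSD, fold changes.

test_that("mean and SE follow the sample-sd / sqrt(n) convention", {
    ms <- meanSE(c(3, 3, 3))
    expect_identical(unname(ms["mean"]), 3)
    expect_identical(unname(ms["se"]), 0)
    ms2 <- meanSE(c(1, 3))
    expect_identical(unname(ms2["mean"]), 2)
    expect_identical(unname(ms2["se"]), 1)   # sd = sqrt(2), se = 1
    expect_true(is.na(meanSE(5)["se"]))
    expect_error(meanSE(numeric()), "at least one")

    set.seed(50)
    x <- rnorm(1000, 7, 3)
    expect_lt(abs(meanSE(x)["mean"] - 7), 4 * 3 / sqrt(1000))
})

test_that("identical group means give F = 0", {
    v <- c(1, 2, 3, 1, 2, 3)
    g <- rep(c("a", "b"), each = 3)
    expect_equal(oneWayAnova(v, g)$F, 0, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected explicitly", {
    expect_error(oneWayAnova(1:4, rep("a", 4)), "two groups")
    expect_error(oneWayAnova(c(1, 2, 3), c("a", "a", "b")), "at least two values")
    expect_error(oneWayAnova(rep(5, 6), rep(c("a", "b"), each = 3)),
                 "degenerate")
})

test_that("ANOVA p agrees with a permutation oracle", {
    set.seed(60)
    v <- c(4.1, 5.3, 3.8, 4.9, 6.0, 5.5, 7.1, 6.2, 4.4, 5.8, 6.6, 5.1)
    g <- rep(c("a", "b", "c"), each = 4)
    res <- oneWayAnova(v, g)
    fObs <- manualF(v, g)
    expect_equal(res$F, fObs, tolerance = 1e-10)
    B <- 20000L
    exceed <- vapply(seq_len(B), function(i) manualF(sample(v), g) >= fObs,
                     logical(1))
    pPerm <- mean(exceed)
    mcSE <- sqrt(pPerm * (1 - pPerm) / B)
    # permutation p and F-distribution p agree within Monte-Carlo error
    # (plus a small allowance for the discreteness of 12-value permutations)
    expect_lt(abs(res$p - pPerm), 4 * mcSE + 0.02)
})

test_that("F is invariant to shifting and scaling the data", {
    set.seed(61)
    v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
    f0 <- oneWayAnova(v, g)$F
    expect_equal(oneWayAnova(v + 100, g)$F, f0, tolerance = 1e-9)
    expect_equal(oneWayAnova(v * 37, g)$F, f0, tolerance = 1e-9)
})

test_that("Tukey p values are symmetric and near 1 for identical groups", {
    v <- c(1, 2, 3, 1.02, 2.01, 2.98, 0.99, 2.02, 3.01)
    g <- rep(c("a", "b", "c"), each = 3)
    tk <- tukeyPairwise(v, g)
    expect_true(all(tk$p_adj > 0.95))
    # relabeling the groups (reversing every pair order) permutes rows but
    # leaves the set of adjusted p values unchanged
    g2 <- c(a = "z", b = "y", c = "x")[g]
    tk2 <- tukeyPairwise(v, g2)
    expect_equal(sort(tk$p_adj), sort(tk2$p_adj), tolerance = 1e-9)
})

test_that("Tukey-adjusted p dominates the unadjusted pairwise comparison", {
    set.seed(62)
    for (rep in 1:10) {
        v <- rnorm(24, sd = 2) + rep(c(0, runif(1, 0, 2), runif(1, 0, 2)),
                                     each = 8)
        g <- rep(c("a", "b", "c"), each = 8)
        tk <- tukeyPairwise(v, g)
        for (i in seq_len(nrow(tk))) {
            pT <- lsdP(v, g, tk$group_a[i], tk$group_b[i])
            expect_gte(tk$p_adj[i], pT - 1e-9)
        }
    }
})

test_that("Tukey p agrees with a resampling studentized-range oracle", {
    set.seed(63)
    v <- c(2.5, 3.1, 2.8, 3.4, 4.9, 5.3, 4.6, 5.0, 3.0, 3.3, 2.7, 3.6)
    g <- rep(c("a", "b", "c"), each = 4)
    tk <- tukeyPairwise(v, g)
    n <- 4; k <- 3; df <- length(v) - k
    s2 <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / df
    gm <- tapply(v, g, mean)
    # Monte-Carlo null distribution of the studentized range
    B <- 40000L
    qNull <- vapply(seq_len(B), function(i) {
        z <- rnorm(k)                       # standardized group means
        sSim <- sqrt(rchisq(1, df) / df)    # independent pooled sd
        (max(z) - min(z)) / sSim
    }, numeric(1))
    for (i in seq_len(nrow(tk))) {
        qObs <- abs(gm[tk$group_a[i]] - gm[tk$group_b[i]]) / sqrt(s2 / n)
        pMC <- mean(qNull >= qObs)
        expect_lt(abs(tk$p_adj[i] - pMC), 0.02)
    }
})

test_that("fold changes reproduce printed ratios with integer rounding", {
    fc <- foldChange(2744, 270)
    expect_equal(fc$ratio, 10.162963, tolerance = 1e-6)
    expect_identical(fc$fold, 10)
    fc2 <- foldChange(2744, 287)
    expect_equal(fc2$ratio, 9.5609756, tolerance = 1e-6)
    expect_identical(fc2$fold, 10)          # round half up
    expect_identical(foldChange(5, 5)$ratio, 1)
    expect_error(foldChange(1, 0), "> 0")
})

test_that("the full comparison report is internally consistent", {
    set.seed(64)
    v <- c(rnorm(10, 270, 80), rnorm(10, 3000, 400), rnorm(10, 340, 90))
    g <- rep(c("CTR-VD", "PS-VD", "PS-AD"), each = 10)
    cmp <- compareGroups(v, g)
    s <- groupSummary(cmp)
    expect_identical(s$n, rep(10L, 3))
    for (i in 1:3)
        expect_equal(s$se[i], sd(v[g == s$group[i]]) / sqrt(10),
                     tolerance = 1e-12)
    fc <- foldChanges(cmp)
    expect_equal(unname(diag(fc)), rep(1, 3))
    expect_equal(fc["PS-VD", "CTR-VD"] * fc["CTR-VD", "PS-VD"], 1,
                 tolerance = 1e-12)
    expect_equal(anovaF(cmp), manualF(v, factor(g)), tolerance = 1e-9)
    expect_identical(nrow(tukeyTable(cmp)), 3L)
})
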
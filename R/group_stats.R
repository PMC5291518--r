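# Group statistics: mean +/- SE, one-way ANOVA with Tukey HSD post-hoc
# pairwise comparisons, pairwise fold changes. The unit of analysis is the
# animal; per-animal values are means over that animal's sections.

#' Mean and standard error of one group
#'
#' @param values numeric vector of per-animal measurements (n >= 1).
#' @return named numeric: \code{mean}, \code{se} (sample sd with n - 1
#'   denominator over sqrt(n); NA for n = 1), \code{n}.
#' @examples
#' meanSE(c(1, 3))   # mean 2, se 1
#' @export
meanSE <- function(values) {
    n <- length(values)
    if (n == 0L) stop("at least one value is required")
    c(mean = mean(values),
      se = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
      n = n)
}

checkGroups <- function(values, groups) {
    stopifnot(length(values) == length(groups))
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stop("at least two groups are required")
    ns <- table(groups)
    if (any(ns < 2L))
        stop("every group needs at least two values; offending group(s): ",
             paste(names(ns)[ns < 2], collapse = ", "))
    within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
    if (within <= 0)
        stop("degenerate input: zero within-group variance")
    groups
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA: the ratio of between- to
#' within-group mean squares on (k - 1, N - k) degrees of freedom, with the
#' p value from the F distribution (fitted via \code{\link[stats]{aov}}).
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length.
#' @return list with \code{F}, \code{p}, \code{df} (numerator, denominator).
#' @export
oneWayAnova <- function(values, groups) {
    groups <- checkGroups(values, groups)
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
         df = c(s[["Df"]][1], s[["Df"]][2]))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based adjusted p values for all group pairs following
#' one-way ANOVA (\code{\link[stats]{TukeyHSD}}). Adjusted p values are
#' symmetric in pair order.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length.
#' @return data.frame with columns group_a, group_b, diff (mean difference
#'   a - b), p_adj.
#' @export
tukeyPairwise <- function(values, groups) {
    groups <- checkGroups(values, groups)
    tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    # group labels may themselves contain '-', so reconstruct the pair
    # names from the factor levels instead of splitting rownames
    cmb <- utils::combn(levels(groups), 2L)
    expected <- paste(cmb[2L, ], cmb[1L, ], sep = "-")
    ord <- match(expected, rownames(tk))
    if (anyNA(ord))
        stop("internal error: unexpected TukeyHSD comparison names")
    data.frame(
        group_a = cmb[2L, ],
        group_b = cmb[1L, ],
        diff = tk[ord, "diff"],
        p_adj = tk[ord, "p adj"],
        row.names = NULL)
}

#' Fold change between two group means
#'
#' @param meanA,meanB group means; \code{meanB} must be positive.
#' @return list with \code{ratio} (meanA / meanB) and \code{fold}
#'   (the ratio rounded half-up to the nearest integer, for "n-fold"
#'   phrasing).
#' @examples
#' foldChange(2744, 270)  # ratio 10.16, reported as a 10-fold increase
#' @export
foldChange <- function(meanA, meanB) {
    if (meanB <= 0) stop("'meanB' must be > 0")
    r <- meanA / meanB
    list(ratio = r, fold = roundHalfUp(r))
}

#' Full group comparison report
#'
#' Per-group mean +/- SE, one-way ANOVA, Tukey HSD pairwise comparisons and
#' the matrix of pairwise fold changes (row mean / column mean; the
#' diagonal is 1).
#'
#' @param values numeric vector of per-animal measurements.
#' @param groups group labels, same length.
#' @return a \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(values, groups) {
    gf <- checkGroups(values, groups)
    lv <- levels(gf)
    summ <- do.call(rbind, lapply(lv, function(g) {
        ms <- meanSE(values[gf == g])
        data.frame(group = g, n = as.integer(ms["n"]), mean = ms["mean"],
                   se = ms["se"], row.names = NULL)
    }))
    an <- oneWayAnova(values, gf)
    tk <- tukeyPairwise(values, gf)
    means <- summ$mean
    fc <- outer(means, means, "/")
    dimnames(fc) <- list(lv, lv)
    new("GroupComparison", summary = summ, anovaF = an$F, anovaP = an$p,
        tukey = tk, foldChanges = fc)
}
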
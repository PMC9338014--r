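#' Paired Wilcoxon signed-rank test with exact small-sample p values
#'
#' Differences of exactly zero are dropped before ranking (Wilcoxon's
#' original treatment); tied absolute differences receive mid-ranks.  For
#' n <= \code{exactMax} nonzero pairs, the p value is exact under the
#' sign-flip null: the distribution of the positive-rank sum W+ over all
#' 2^n sign assignments is computed by convolution over the (doubled,
#' hence integer) mid-ranks.  For larger n a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative \code{"greater"} (x tends to exceed y),
#'   \code{"less"}, or \code{"two.sided"}.
#' @param exactMax largest n for which the exact distribution is used.
#' @return list with \code{W} (positive-rank sum), \code{p}, \code{n}
#'   (nonzero pairs), \code{degenerate} (TRUE when all differences are
#'   zero, in which case p = 1).
#' @export
wilcoxonSignedRank <- function(x, y,
                               alternative = c("greater", "less",
                                               "two.sided"),
                               exactMax = 15L) {
    alternative <- match.arg(alternative)
    stopifnot(length(x) == length(y))
    d <- x - y
    d <- d[!is.na(d)]
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(list(W = 0, p = 1, n = 0L, degenerate = TRUE))
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    if (n <= exactMax) {
        p <- signFlipTail(r, W, alternative)
    } else {
        mu <- n * (n + 1) / 4
        ties <- table(r)
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(ties^3 - ties) / 48
        z <- switch(alternative,
            greater   = (W - mu - 0.5) / sqrt(sigma2),
            less      = (W - mu + 0.5) / sqrt(sigma2),
            two.sided = (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2))
        p <- switch(alternative,
            greater   = stats::pnorm(z, lower.tail = FALSE),
            less      = stats::pnorm(z),
            two.sided = 2 * stats::pnorm(-abs(z)))
        p <- min(1, p)
    }
    list(W = W, p = p, n = n, degenerate = FALSE)
}

# Exact tail probability of the positive-rank sum under random sign flips.
# Mid-ranks are multiples of 1/2, so doubling gives an integer support and
# the 2^n enumeration collapses to a polynomial convolution.
signFlipTail <- function(r, W, alternative) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[k+1] = #assignments with doubled W+ == k
    f[1L] <- 1
    for (a in r2) {
        g <- f
        idx <- (a + 1L):(total + 1L)
        g[idx] <- g[idx] + f[idx - a]
        f <- g
    }
    nAssign <- 2^length(r)
    w2 <- as.integer(round(2 * W))
    pGe <- sum(f[(w2 + 1L):(total + 1L)]) / nAssign
    pLe <- sum(f[seq_len(w2 + 1L)]) / nAssign
    switch(alternative,
        greater   = pGe,
        less      = pLe,
        two.sided = min(1, 2 * min(pGe, pLe)))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment; the mapping back to input order is preserved.
#'
#' @param p numeric vector of p values in (0, 1].
#' @param q FDR level used for the significance flag.
#' @return list with \code{p_adj} and logical \code{significant}
#'   (\code{p_adj < q}).
#' @export
bhAdjust <- function(p, q = 0.05) {
    if (!length(p)) return(list(p_adj = numeric(), significant = logical()))
    stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
    adj <- stats::p.adjust(p, method = "BH")
    list(p_adj = adj, significant = !is.na(adj) & adj < q)
}

#' Kruskal-Wallis H test across labeled groups
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length; at least two groups with two
#'   or more values each.
#' @return list with \code{H} (tie-corrected statistic), \code{df},
#'   \code{p}.
#' @export
kruskalWallis <- function(values, groups) {
    groups <- as.factor(droplevels(as.factor(groups)))
    stopifnot(length(values) == length(groups))
    cnt <- table(groups)
    if (length(cnt) < 2) stop("need at least two groups")
    if (any(cnt < 2)) stop("every group needs at least two values")
    if (length(unique(values)) == 1L)
        stop("all observations identical: H is undefined (tie correction ",
             "denominator is zero)")
    kt <- stats::kruskal.test(values, groups)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Dunn's pairwise post-hoc comparisons
#'
#' Rank-based z tests between all pairs of groups after a Kruskal-Wallis
#' test, with the usual tie correction and (by default) Bonferroni
#' adjustment by the number of pairs.
#'
#' @inheritParams kruskalWallis
#' @param correction \code{"bonferroni"} or \code{"none"}.
#' @return data.frame with columns \code{groupA}, \code{groupB}, \code{z},
#'   \code{p_raw}, \code{p_adj}.
#' @seealso [groupLetters()] to derive shared-letter displays.
#' @export
dunnPairwise <- function(values, groups, correction = c("bonferroni",
                                                        "none")) {
    correction <- match.arg(correction)
    groups <- droplevels(as.factor(groups))
    stopifnot(length(values) == length(groups))
    if (nlevels(groups) < 2) stop("need at least two groups")
    if (any(table(groups) < 2)) stop("every group needs at least two values")
    N <- length(values)
    r <- rank(values)
    ties <- table(r)
    tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
    meanR <- tapply(r, groups, mean)
    n <- tapply(r, groups, length)
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    z <- apply(pairs, 2, function(pr) {
        se <- sqrt((N * (N + 1) / 12 - tieTerm) *
                   (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
        (meanR[[pr[1]]] - meanR[[pr[2]]]) / se
    })
    pRaw <- 2 * stats::pnorm(-abs(z))
    mult <- if (correction == "bonferroni") ncol(pairs) else 1
    data.frame(groupA = pairs[1, ], groupB = pairs[2, ], z = z,
               p_raw = pRaw, p_adj = pmin(1, pRaw * mult),
               row.names = NULL)
}

#' One-sided Fisher's exact test for enrichment of replaced-chromosome
#' subunits among unstable complexes
#'
#' Builds the 2x2 table (unstable vs stable) x (contains a subunit encoded
#' on a replaced chromosome vs not) over all tested complexes and tests
#' enrichment with a one-sided hypergeometric tail.
#'
#' @param calls data.frame from [callUnstableComplexes()] (columns
#'   \code{complex_id}, \code{tested}, \code{unstable}).
#' @param compendium A [ComplexCompendium-class].
#' @param annot annotation data.frame.
#' @param replaced integer vector of replaced chromosomes.
#' @return list with \code{table}, \code{odds_ratio}, \code{p}.
#' @export
enrichmentFisher <- function(calls, compendium, annot, replaced) {
    tested <- calls[calls$tested, , drop = FALSE]
    if (!nrow(tested)) stop("no tested complexes")
    m <- annotatedMembership(compendium, annot)
    chrComplexes <- unique(m$complex_id[m$chromosome %in% replaced])
    hasChr <- tested$complex_id %in% chrComplexes
    tab <- table(
        factor(ifelse(tested$unstable, "unstable", "stable"),
               levels = c("unstable", "stable")),
        factor(ifelse(hasChr, "chr", "non_chr"),
               levels = c("chr", "non_chr")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(table = tab, odds_ratio = NA_real_, p = 1))
    ft <- stats::fisher.test(tab, alternative = "greater")
    list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Compare two independent Spearman correlations with Fisher's r-to-z
#'
#' z = (atanh(rhoA) - atanh(rhoB)) / sqrt(1/(nA-3) + 1/(nB-3)), with a
#' two-sided normal p value.  Intended for correlations computed on
#' disjoint groups.
#'
#' @param rhoA,rhoB correlation coefficients with |rho| < 1.
#' @param nA,nB group sizes (>= 4).
#' @return list with \code{z}, \code{p}.
#' @export
fisherRToZ <- function(rhoA, nA, rhoB, nB) {
    stopifnot(nA >= 4, nB >= 4)
    if (abs(rhoA) >= 1 || abs(rhoB) >= 1)
        stop("|rho| must be < 1 for the r-to-z transform")
    z <- (atanh(rhoA) - atanh(rhoB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman rank correlation with mid-rank ties
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return rho.
#' @export
spearmanRho <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        stop("Spearman correlation undefined for a constant vector")
    stats::cor(x, y, method = "spearman")
}

#' One-sided two-sample t test
#'
#' Welch's unequal-variance t by default (replicate variances differ
#' between lines); set \code{varEqual = TRUE} for the pooled-variance
#' Student form.  When both groups have zero variance and equal means the
#' comparison is degenerate and p = 0.5 is returned with a flag.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param alternative \code{"greater"} tests a > b.
#' @param varEqual pooled-variance Student test instead of Welch.
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
oneSidedT <- function(a, b, alternative = c("greater", "less"),
                      varEqual = FALSE) {
    alternative <- match.arg(alternative)
    stopifnot(length(a) >= 2, length(b) >= 2)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b))
            return(list(t = 0, df = NA_real_, p = 0.5, degenerate = TRUE))
        p <- if ((mean(a) > mean(b)) == (alternative == "greater")) 0 else 1
        return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                    p = p, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, alternative = alternative,
                        var.equal = varEqual)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}
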
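test_that("signed-rank test matches sign-flip enumeration and known values", {
    x <- c(3, 1, 4, 1, 5)
    expect_equal(wilcoxonSignedRank(x, x)$p, 1)
    expect_true(wilcoxonSignedRank(x, x)$degenerate)

    y <- stats::rnorm(6)
    r <- wilcoxonSignedRank(y + 1, y)
    expect_equal(r$p, 1 / 2^6)

    set.seed(5)
    for (n in 2:10) {
        for (rep in 1:5) {
            a <- round(stats::rnorm(n), 1)  # rounding induces ties/zeros
            b <- round(stats::rnorm(n), 1)
            for (alt in c("greater", "less")) {
                expect_equal(wilcoxonSignedRank(a, b, alt)$p,
                             enumSignedRankP(a, b, alt),
                             info = paste("n =", n, alt))
            }
        }
    }
})

test_that("signed-rank agrees with stats::wilcox.test on tie-free data", {
    set.seed(6)
    for (n in c(8, 12, 25, 40)) {
        a <- stats::rnorm(n)
        b <- stats::rnorm(n)
        ours <- wilcoxonSignedRank(a, b, "greater")
        ref <- stats::wilcox.test(a, b, paired = TRUE,
                                  alternative = "greater",
                                  exact = n <= 15, correct = TRUE)
        expect_equal(ours$W, unname(ref$statistic))
        expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(0.03)$p_adj, 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04))$p_adj,
                 rep(0.04, 4))
    set.seed(7)
    for (i in 1:10) {
        p <- stats::runif(sample(3:40, 1))
        adj <- bhAdjust(p)$p_adj
        expect_equal(adj, stepUpBH(p))
        expect_true(all(adj >= p))
        o <- order(p)
        expect_true(all(diff(adj[o]) >= -1e-12))
    }
    expect_equal(bhAdjust(numeric())$p_adj, numeric())
})

test_that("Kruskal-Wallis equals the closed-form rank formula", {
    v <- c(1, 2, 3, 4)
    g <- c("a", "a", "b", "b")
    res <- kruskalWallis(v, g)
    expect_equal(res$H, 12 / (4 * 5) * (2 * (1.5 - 2.5)^2 +
                                        2 * (3.5 - 2.5)^2))
    expect_equal(res$df, 1)

    set.seed(8)
    v2 <- stats::rnorm(30)
    g2 <- rep(c("a", "b", "c"), 10)
    r2 <- kruskalWallis(v2, g2)
    N <- 30
    rk <- rank(v2)
    H <- 12 / (N * (N + 1)) *
        sum(tapply(rk, g2, function(z) length(z) *
                       (mean(z) - (N + 1) / 2)^2))
    expect_equal(r2$H, H)  # no ties, correction factor is 1

    expect_error(kruskalWallis(rep(1, 6), rep(c("a", "b"), 3)),
                 "identical")
    expect_error(kruskalWallis(1:3, c("a", "a", "b")), "at least two")
})

test_that("Dunn pairwise z tests behave on shifted and identical groups", {
    set.seed(9)
    base <- stats::rnorm(30)
    v <- c(base, base, base + 50)
    g <- rep(c("a", "b", "c"), each = 30)
    dn <- dunnPairwise(v, g)
    expect_equal(nrow(dn), 3L)
    expect_equal(dn$p_adj, pmin(1, dn$p_raw * 3))
    ab <- dn[dn$groupA == "a" & dn$groupB == "b", ]
    expect_gt(ab$p_adj, 0.05)   # identical groups: not significant
    expect_lt(max(dn$p_adj[dn$groupA == "c" | dn$groupB == "c"]), 0.01)

    pm <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"),
                                          c("a", "b", "c")))
    pm["c", c("a", "b")] <- pm[c("a", "b"), "c"] <- 0.001
    lets <- groupLetters(pm)
    expect_equal(lets[["a"]], lets[["b"]])
    expect_false(lets[["c"]] == lets[["a"]])
})

test_that("enrichment Fisher test equals hypergeometric tail enumeration", {
    # 3 unstable all chr-containing, 3 stable all not: p = 1/20
    comp <- ComplexCompendium(data.frame(
        complex_id = rep(paste0("C", 1:6), each = 2),
        protein_id = paste0("P", 1:12)))
    an <- data.frame(gene_id = paste0("G", 1:12),
                     protein_id = paste0("P", 1:12),
                     chromosome = rep(c(16L, 1L), each = 6))
    calls <- data.frame(complex_id = paste0("C", 1:6),
                        tested = TRUE,
                        unstable = rep(c(TRUE, FALSE), each = 3))
    res <- enrichmentFisher(calls, comp, an, 16L)
    expect_equal(res$p, 1 / 20)
    expect_equal(res$p, hyperTailP(res$table))

    allUn <- transform(calls, unstable = TRUE)
    expect_equal(enrichmentFisher(allUn, comp, an, 16L)$p, 1)

    set.seed(10)
    for (i in 1:20) {
        calls2 <- data.frame(complex_id = paste0("C", 1:6),
                             tested = TRUE,
                             unstable = sample(c(TRUE, FALSE), 6,
                                               replace = TRUE))
        res2 <- enrichmentFisher(calls2, comp, an, 16L)
        if (!is.na(res2$odds_ratio))
            expect_equal(res2$p, hyperTailP(res2$table))
    }
})

test_that("Fisher r-to-z matches the closed form and is antisymmetric", {
    same <- fisherRToZ(0.4, 50, 0.4, 80)
    expect_equal(same$z, 0)
    expect_equal(same$p, 1)

    r <- fisherRToZ(0.5, 103, 0.0, 103)
    expect_equal(r$z, atanh(0.5) / sqrt(2 / 100), tolerance = 1e-12)
    expect_equal(r$z, 3.885, tolerance = 1e-3)

    a <- fisherRToZ(0.7, 40, 0.2, 60)
    b <- fisherRToZ(0.2, 60, 0.7, 40)
    expect_equal(a$z, -b$z)
    expect_equal(a$p, b$p)
    expect_error(fisherRToZ(1, 10, 0, 10), "r-to-z")
})

test_that("Spearman rho handles monotone transforms and ties", {
    x <- stats::runif(20)
    expect_equal(spearmanRho(x, exp(x)), 1)
    expect_equal(spearmanRho(x, -x^3), -1)
    set.seed(12)
    a <- sample(1:5, 15, replace = TRUE)
    b <- sample(1:5, 15, replace = TRUE)
    if (length(unique(a)) > 1 && length(unique(b)) > 1)
        expect_equal(spearmanRho(a, b),
                     stats::cor(rank(a), rank(b)))  # Pearson-on-ranks
    expect_equal(spearmanRho(x, 2 * x + 1), spearmanRho(x, log(x + 1)))
    expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
})

test_that("one-sided t matches the Welch closed form with degenerate guard", {
    same <- oneSidedT(c(2, 2), c(2, 2))
    expect_equal(same$p, 0.5)
    expect_true(same$degenerate)

    big <- oneSidedT(c(100, 100.1, 99.9), c(1, 1.1, 0.9))
    expect_lt(big$p, 1e-6)

    set.seed(13)
    a <- stats::rnorm(6); b <- stats::rnorm(8, 1)
    res <- oneSidedT(a, b, "greater")
    se <- sqrt(stats::var(a) / 6 + stats::var(b) / 8)
    tstat <- (mean(a) - mean(b)) / se
    df <- se^4 / ((stats::var(a) / 6)^2 / 5 + (stats::var(b) / 8)^2 / 7)
    expect_equal(res$t, tstat)
    expect_equal(res$df, df)
    expect_equal(res$p, stats::pt(tstat, df, lower.tail = FALSE))
})
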
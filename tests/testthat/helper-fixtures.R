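# Fixtures are built in code; files go through tempfiles.

toyAnnotation <- function() {
    data.frame(
        gene_id = paste0("G", 1:6),
        protein_id = paste0("P", 1:6),
        chromosome = c(1L, 2L, 3L, 3L, 16L, 16L))
}

toyCompendium <- function() {
    ComplexCompendium(data.frame(
        complex_id = c("C1", "C1", "C2", "C2"),
        protein_id = c("P1", "P2", "P3", "P4")))
}

# random normalized percent matrices (rows sum to 100)
randomPatterns <- function(n, f = 27L) {
    m <- matrix(stats::rexp(n * f), n, f,
                dimnames = list(sprintf("P%03d", seq_len(n)), NULL))
    100 * m / rowSums(m)
}

percentSet <- function(heavyPct, lightPct) {
    ElutionSet(heavyPct, lightPct, unit = "percent")
}

intensitySet <- function(heavy, light, concentration = NULL) {
    ElutionSet(heavy, light, concentration = concentration)
}

# write a compendium/annotation/intensity tsv to a tempfile
writeTempTsv <- function(df) {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

# independent sign-flip enumeration oracle for the paired signed-rank test
enumSignedRankP <- function(x, y, alternative = "greater") {
    d <- (x - y)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) return(1)
    r <- rank(abs(d))
    Wobs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    Wall <- apply(signs, 1, function(s) sum(r[s]))
    switch(alternative,
        greater = mean(Wall >= Wobs),
        less = mean(Wall <= Wobs))
}

# definitional BH step-up oracle: adj_(i) = min_{j >= i} p_(j) * m / j
stepUpBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- rev(cummin(rev(pmin(1, ps * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- adj
    out
}

# hypergeometric upper-tail oracle for a one-sided 2x2 Fisher test
hyperTailP <- function(tab) {
    a <- tab[1, 1]
    sum(stats::dhyper(a:min(sum(tab[1, ]), sum(tab[, 1])),
                      sum(tab[1, ]), sum(tab[2, ]), sum(tab[, 1])))
}

# small EPD-table generator for complex-level test checks: nComplexes
# complexes of a given size, control EPD baseline plus a planted shift on
# the first nPlanted complexes
epdTablePair <- function(nComplexes, size, nPlanted, shift, noiseSd = 3,
                         baseline = 25) {
    ids <- sprintf("P%04d", seq_len(nComplexes * size))
    comp <- ComplexCompendium(data.frame(
        complex_id = rep(sprintf("C%02d", seq_len(nComplexes)),
                         each = size),
        protein_id = ids))
    ctrl <- abs(stats::rnorm(length(ids), baseline, noiseSd))
    planted <- rep(c(TRUE, FALSE),
                   c(nPlanted, nComplexes - nPlanted))[
        rep(seq_len(nComplexes), each = size)]
    exp <- abs(ctrl + ifelse(planted, shift, 0) +
               stats::rnorm(length(ids), 0, noiseSd))
    list(compendium = comp,
         exp = data.frame(protein_id = ids, epd = exp),
         ctrl = data.frame(protein_id = ids, epd = ctrl),
         plantedIds = sprintf("C%02d", seq_len(nPlanted)))
}
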
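test_that("loadCompendium collapses duplicates and counts complexes", {
    path <- writeTempTsv(data.frame(
        complex_id = c("C1", "C1", "C2", "C2", "C2"),
        protein_id = c("P1", "P2", "P2", "P3", "P3")))
    cc <- suppressMessages(loadCompendium(path))
    expect_s4_class(cc, "ComplexCompendium")
    expect_equal(nComplexes(cc), 2L)
    expect_equal(nSubunits(cc), 3L)
    expect_equal(sort(memberList(cc)$C2), c("P2", "P3"))

    empty <- writeTempTsv(data.frame(complex_id = character(),
                                     protein_id = character()))
    cc0 <- suppressMessages(loadCompendium(empty))
    expect_equal(nComplexes(cc0), 0L)

    single <- writeTempTsv(data.frame(complex_id = "C1",
                                      protein_id = "P1"))
    expect_warning(suppressMessages(loadCompendium(single)),
                   "<2 members")
    bad <- writeTempTsv(data.frame(foo = "C1", protein_id = "P1"))
    expect_error(loadCompendium(bad), "complex_id")
})

test_that("annotation loading converts Roman numerals and validates", {
    path <- writeTempTsv(data.frame(
        gene_id = c("G1", "G2", "G3"),
        protein_id = c("P1", "P2", "P3"),
        chromosome = c("IV", "chrXVI", "2")))
    an <- loadAnnotation(path)
    expect_equal(an$chromosome, c(4L, 16L, 2L))
    expect_error(chromosomeToInt("chrQ"), "unparseable")
    dup <- writeTempTsv(data.frame(gene_id = c("G1", "G1"),
                                   protein_id = c("P1", "P2"),
                                   chromosome = c(1, 2)))
    expect_error(loadAnnotation(dup), "unique")
})

test_that("chromosome complex counting matches hand counts and saturates", {
    an <- toyAnnotation()
    cc <- toyCompendium()  # C1:{P1@1,P2@2}, C2:{P3@3,P4@3}
    expect_equal(countComplexesOnChromosomes(cc, an, 1L), 1L)
    expect_equal(countComplexesOnChromosomes(cc, an, 3L), 1L)
    expect_equal(countComplexesOnChromosomes(cc, an, 1:16), 2L)
    expect_equal(countComplexesOnChromosomes(cc, an, 7L), 0L)
    bad <- ComplexCompendium(data.frame(complex_id = c("C1", "C1"),
                                        protein_id = c("P1", "P99")))
    expect_error(countComplexesOnChromosomes(bad, an, 1L), "P99")
})

test_that("chromosome complex counting is monotone in the replaced set", {
    set.seed(11)
    cfg <- simulationConfig(seed = 11, nGenes = 400L, nComplexes = 12L)
    ac <- simulateAnnotationAndCompendium(cfg)
    counts <- vapply(1:16, function(k)
        countComplexesOnChromosomes(ac$compendium, ac$annot, 1:k),
        integer(1))
    expect_true(all(diff(counts) >= 0))
    expect_equal(counts[16], nComplexes(ac$compendium))
})

test_that("complexProteinRatio matches a brute-force set oracle", {
    an <- data.frame(gene_id = paste0("G", 1:10),
                     protein_id = paste0("P", 1:10),
                     chromosome = rep(1L, 10))
    cc <- ComplexCompendium(data.frame(
        complex_id = c("C1", "C1", "C2", "C2"),
        protein_id = c("P1", "P2", "P3", "P4")))
    expect_equal(complexProteinRatio(cc, an, 1L), 0.4)
    an2 <- toyAnnotation()
    cc2 <- toyCompendium()
    expect_equal(complexProteinRatio(cc2, an2, 16L), 0)
    expect_error(complexProteinRatio(cc2, an2, 9L), "no annotated")

    set.seed(42)
    for (i in 1:10) {
        n <- 40
        an3 <- data.frame(gene_id = paste0("G", 1:n),
                          protein_id = paste0("P", 1:n),
                          chromosome = sample(1:16, n, replace = TRUE))
        mem <- data.frame(
            complex_id = rep(paste0("C", 1:5), each = 3),
            protein_id = sample(an3$protein_id, 15))
        cc3 <- ComplexCompendium(mem)
        repl <- sample(1:16, 4)
        onChr <- an3$protein_id[an3$chromosome %in% repl]
        if (!length(onChr)) next
        oracle <- length(intersect(onChr, mem$protein_id)) / length(onChr)
        expect_equal(complexProteinRatio(cc3, an3, repl), oracle)
    }
})

test_that("protein group labels respect precedence and partition", {
    an <- toyAnnotation()
    cc <- toyCompendium()
    g <- assignProteinGroups(c("P1", "P3", "P5"), cc, an, replaced = 1L)
    expect_equal(as.character(g),
                 c("chr_complex", "non_chr_complex", "non_complex"))
    # P2 sits in chr-complex C1 (via P1@chr1); both-membership proteins
    # take the chr label under the default rule
    ccBoth <- ComplexCompendium(data.frame(
        complex_id = c("C1", "C1", "C2", "C2"),
        protein_id = c("P1", "P2", "P2", "P3")))
    gBoth <- assignProteinGroups("P2", ccBoth, an, replaced = 1L)
    expect_equal(as.character(gBoth), "chr_complex")
    gBoth2 <- assignProteinGroups("P2", ccBoth, an, replaced = 1L,
                                  bothRule = "non_chr_complex")
    expect_equal(as.character(gBoth2), "non_chr_complex")

    # partition: chr + non-chr = complex proteins; + non-complex = total
    cfg <- simulationConfig(seed = 3, nGenes = 500L, nComplexes = 15L)
    ac <- simulateAnnotationAndCompendium(cfg)
    g2 <- assignProteinGroups(ac$annot$protein_id, ac$compendium,
                              ac$annot, replaced = 16L)
    tab <- table(g2)
    expect_equal(sum(tab), nrow(ac$annot))
    expect_equal(sum(tab[c("chr_complex", "non_chr_complex")]),
                 nSubunits(ac$compendium))
})
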
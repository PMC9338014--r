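test_that("generators are byte-identical under a fixed seed", {
    cfg <- simulationConfig(seed = 99, nGenes = 300L, nComplexes = 8L)
    a1 <- simulateAnnotationAndCompendium(cfg)
    a2 <- simulateAnnotationAndCompendium(cfg)
    expect_identical(a1, a2)
    c1 <- simulateCofractionation(a1$annot, a1$compendium, cfg)
    c2 <- simulateCofractionation(a1$annot, a1$compendium, cfg)
    expect_identical(assay(c1$experiment, "light"),
                     assay(c2$experiment, "light"))
    expect_identical(c1$truth, c2$truth)
    t1 <- simulateTranscriptome(a1$annot, cfg)
    t2 <- simulateTranscriptome(a1$annot, cfg)
    expect_identical(t1$fcMatrix, t2$fcMatrix)
    p1 <- simulatePhenotypes(a1$annot, a1$compendium, cfg)
    p2 <- simulatePhenotypes(a1$annot, a1$compendium, cfg)
    expect_identical(p1$records, p2$records)
    # different seed, different draw
    cfgB <- simulationConfig(seed = 100, nGenes = 300L, nComplexes = 8L)
    expect_false(identical(
        simulateAnnotationAndCompendium(cfgB)$annot$chromosome,
        a1$annot$chromosome))
})

test_that("complex sizes respect bounds and chromosomes are uniform", {
    cfg <- simulationConfig(seed = 5, nGenes = 6000L, nComplexes = 150L,
                            sizeMin = 3L, sizeMax = 12L)
    ac <- simulateAnnotationAndCompendium(cfg)
    sz <- lengths(memberList(ac$compendium))
    expect_true(all(sz >= 3 & sz <= 12))
    # occupancy approx uniform over 16 chromosomes
    cs <- suppressWarnings(stats::chisq.test(table(ac$annot$chromosome)))
    expect_gt(cs$p.value, 0.001)
    # infeasible demand is rejected
    expect_error(simulationConfig(seed = 1, nGenes = 100L,
                                  nComplexes = 60L, sizeMax = 30L),
                 "exceeds")
})

test_that("noiseless null co-fractionation gives identical channels", {
    cfg <- simulationConfig(seed = 6, nGenes = 300L, nComplexes = 8L,
                            delta = 0, gamma = 1, noiseCV = 0)
    ac <- simulateAnnotationAndCompendium(cfg)
    cf <- simulateCofractionation(ac$annot, ac$compendium, cfg)
    pat <- elutionPatterns(concentrationCorrect(cf$experiment))
    epd <- computeEPD(pat)
    expect_true(all(epd$epd < 1e-9))
    expect_false(any(cf$truth$planted_unstable))
})

test_that("full destabilization with tight peaks hits the closed-form EPD", {
    # delta = 1, sigma -> 0, no noise: planted subunits put alphaRef of
    # their heavy mass at the complex peak and all light mass at the
    # monomer peak, so EPD = 2 * alphaRef * 100 when the peaks differ
    cfg <- simulationConfig(seed = 7, nGenes = 400L, nComplexes = 10L,
                            sizeMin = 8L, sizeMax = 20L, delta = 1,
                            noiseCV = 0, sigmaPeak = 0.05,
                            plantFraction = 1, plantMinSize = 2L)
    ac <- simulateAnnotationAndCompendium(cfg)
    cf <- simulateCofractionation(ac$annot, ac$compendium, cfg)
    pat <- elutionPatterns(concentrationCorrect(cf$experiment))
    epd <- computeEPD(pat)
    tr <- cf$truth
    planted <- tr$complex_id[tr$planted_unstable & tr$peak < 24]
    members <- memberList(ac$compendium)
    for (cid in planted) {
        vals <- epd$epd[epd$protein_id %in% members[[cid]]]
        expect_equal(vals, rep(2 * 0.9 * 100, length(vals)),
                     tolerance = 1e-6)
    }
})

test_that("transcriptome truth classes drive recovery and masking", {
    cfg <- simulationConfig(seed = 8, nGenes = 800L, nComplexes = 10L)
    ac <- simulateAnnotationAndCompendium(cfg)
    tr <- simulateTranscriptome(ac$annot, cfg, effect = 2, nullSd = 0.15)
    status <- deStatusMatrix(tr$fcTable, ac$annot, tr$lines)
    common <- commonResponse(status, k = 4)
    planted <- tr$truth$gene_id[tr$truth$planted_class == "common_up"]
    hit <- common$class[match(planted, common$gene_id)] == "common_up"
    expect_gt(mean(hit), 0.9)

    # genes on a line's replaced chromosome are never called on that line
    for (ln in names(tr$lines)) {
        genesOn <- ac$annot$gene_id[ac$annot$chromosome %in%
                                        tr$lines[[ln]]]
        expect_true(all(is.na(status[genesOn, ln])))
    }

    # zero-effect, zero-stress config: essentially nothing called common
    trNull <- simulateTranscriptome(ac$annot, cfg, nCommonUp = 0L,
                                    nCommonDown = 0L, esrStress = 0)
    commonNull <- commonResponse(
        deStatusMatrix(trNull$fcTable, ac$annot, trNull$lines), k = 4)
    expect_equal(sum(commonNull$class %in% c("common_up",
                                             "common_down")), 0L)
})

test_that("phenotype generator couples counts and supports recovery", {
    cfg <- simulationConfig(seed = 9, nGenes = 1000L, nComplexes = 30L)
    ac <- simulateAnnotationAndCompendium(cfg)
    ph <- simulatePhenotypes(ac$annot, ac$compendium, cfg, sd = 0)
    # sd = 0: phenotype is a deterministic monotone map of the count
    res <- phenotypeComplexCorrelation(ph$records, "fitness_defect")
    expect_equal(res$rho, 1)
    # growth curves reproduce the per-line doubling time
    ln <- ph$records$line[1]
    g <- ph$growth[ph$growth$line == ln, ]
    dt <- maxGrowthRate(g$time_min, g$od)$doubling_time
    expect_lt(abs(dt - (90 + 3 * ph$records$complex_count[1])) /
                  dt, 0.1)
})
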
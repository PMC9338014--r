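#' Build a SimulationConfig with validated defaults
#'
#' The defaults describe the simulated study: a 2000-protein proteome on
#' 16 chromosomes, 60 disjoint complexes with a truncated-geometric size
#' distribution on [2, 30], 27 SEC fractions, a reference assembled
#' fraction of 0.9, destabilization effect 0.7 on planted complexes,
#' log-normal intensity noise with CV 0.2, and chromosome 16 replaced.
#'
#' @param seed integer master seed; every generator derives a named
#'   substream from it.
#' @param nGenes,nChromosomes,nComplexes genome dimensions.
#' @param sizeMin,sizeMax,sizeGeomP complex-size distribution parameters.
#' @param nFractions SEC fractions (27).
#' @param alphaRef reference-channel assembled fraction in [0,1].
#' @param delta planted destabilization effect in [0,1].
#' @param gamma planted degradation factor in (0,1].
#' @param sigmaPeak elution-peak spread in fractions.
#' @param noiseCV log-normal multiplicative noise CV.
#' @param dropoutThreshold intensities below this are zeroed (0 = off).
#' @param replaced replaced chromosome set.
#' @param plantFraction fraction of chr-complexes planted when
#'   \code{nPlanted} is NA.
#' @param nPlanted exact number of planted complexes (NA = use fraction).
#' @param plantMinSize minimum size of a plantable complex.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nGenes = 2000L,
                             nChromosomes = 16L, nComplexes = 60L,
                             sizeMin = 2L, sizeMax = 30L,
                             sizeGeomP = 0.35, nFractions = 27L,
                             alphaRef = 0.9, delta = 0.7, gamma = 1,
                             sigmaPeak = 1.2, noiseCV = 0.2,
                             dropoutThreshold = 0, replaced = 16L,
                             plantFraction = 0.3,
                             nPlanted = NA_integer_,
                             plantMinSize = 2L) {
    new("SimulationConfig",
        seed = as.integer(seed), nGenes = as.integer(nGenes),
        nChromosomes = as.integer(nChromosomes),
        nComplexes = as.integer(nComplexes),
        sizeMin = as.integer(sizeMin), sizeMax = as.integer(sizeMax),
        sizeGeomP = sizeGeomP, nFractions = as.integer(nFractions),
        alphaRef = alphaRef, delta = delta, gamma = gamma,
        sigmaPeak = sigmaPeak, noiseCV = noiseCV,
        dropoutThreshold = dropoutThreshold,
        replaced = as.integer(replaced), plantFraction = plantFraction,
        nPlanted = as.integer(nPlanted),
        plantMinSize = as.integer(plantMinSize))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: seed", object@seed, "|", object@nGenes,
        "genes,", object@nComplexes, "complexes,", object@nFractions,
        "fractions\n")
    cat("  alphaRef", object@alphaRef, "delta", object@delta,
        "gamma", object@gamma, "CV", object@noiseCV,
        "| replaced chr", paste(object@replaced, collapse = "+"), "\n")
})

# Named substream: every generator reseeds deterministically from the
# master seed and its stage name, so stages are independent yet
# reproducible.
stageSeed <- function(seed, stage) {
    (as.double(seed) * 48271 + sum(utf8ToInt(stage)) * 7919) %% 2147483647
}

#' Simulate a gene annotation and a disjoint complex compendium
#'
#' Genes are assigned to chromosomes uniformly; complex sizes are drawn
#' from sizeMin + Geometric(sizeGeomP) truncated at sizeMax, and members
#' are sampled without replacement from the gene pool so complexes are
#' disjoint (planted effects then have unambiguous ground truth).
#'
#' @param config A [SimulationConfig-class].
#' @return list with \code{annot} (data.frame) and \code{compendium}
#'   ([ComplexCompendium-class]).
#' @export
simulateAnnotationAndCompendium <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(stageSeed(config@seed, "annotation"))
    n <- config@nGenes
    annot <- data.frame(
        gene_id = sprintf("G%04d", seq_len(n)),
        protein_id = sprintf("P%04d", seq_len(n)),
        chromosome = sample.int(config@nChromosomes, n, replace = TRUE))
    sizes <- pmin(config@sizeMax,
                  config@sizeMin + stats::rgeom(config@nComplexes,
                                                config@sizeGeomP))
    if (sum(sizes) > n)
        stop("complex membership demand exceeds the gene pool")
    members <- sample(annot$protein_id, sum(sizes))
    membership <- data.frame(
        complex_id = rep(sprintf("CPX%03d", seq_len(config@nComplexes)),
                         times = sizes),
        protein_id = members)
    list(annot = annot, compendium = ComplexCompendium(membership))
}

# SEC elutes large species first: complex peak fraction decreases with
# complex size through a fixed monotone map (size 30 -> fraction 3,
# monomers -> fraction 24).
peakForSize <- function(size, sizeMin = 2L, sizeMax = 30L) {
    pmax(3, pmin(24, round(24 - 21 * (size - 1) / (sizeMax - 1))))
}

monomerPeak <- 24

gaussianProfile <- function(peak, sigma, nFractions) {
    w <- stats::dnorm(seq_len(nFractions), mean = peak, sd = sigma)
    w / sum(w)
}

lognormNoise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate SEC-SILAC co-fractionation tables with planted effects
#'
#' Each complex elutes at a size-dependent peak fraction; a subunit's
#' noiseless profile is a two-component Gaussian mixture, alpha at the
#' complex peak plus (1 - alpha) at the monomer peak, discretized over the
#' fraction grid.  The heavy (reference) channel uses alphaRef; in planted
#' complexes the light channel uses alphaRef * (1 - delta) (partial
#' disassembly) and its total intensity is scaled by gamma (degradation).
#' Non-complex proteins elute monomer-only in both channels.
#' Multiplicative log-normal noise (CV) is applied per cell and values
#' below the dropout threshold are zeroed.  The control set is two
#' independent noisy draws of the reference model.  The emitted tables are
#' "uncorrected": intensities are divided by the per-fraction peptide
#' concentrations they carry, so [concentrationCorrect()] restores them.
#'
#' @param annot,compendium from [simulateAnnotationAndCompendium()].
#' @param config A [SimulationConfig-class].
#' @return list with \code{experiment} and \code{control}
#'   ([ElutionSet-class]) and \code{truth} (per-complex data.frame with
#'   \code{planted}, \code{planted_unstable}, \code{delta}, \code{gamma}).
#' @export
simulateCofractionation <- function(annot, compendium, config) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(stageSeed(config@seed, "cofractionation"))
    nf <- config@nFractions
    prot <- annot$protein_id
    members <- memberList(compendium)
    sizes <- lengths(members)
    peaks <- stats::setNames(
        peakForSize(sizes, config@sizeMin, config@sizeMax), names(sizes))

    chrComplexes <- names(members)[vapply(members, function(p) {
        any(annot$chromosome[match(p, annot$protein_id)] %in%
                config@replaced)
    }, logical(1))]
    eligible <- intersect(chrComplexes,
                          names(sizes)[sizes >= config@plantMinSize])
    nPlant <- if (is.na(config@nPlanted))
        round(config@plantFraction * length(eligible))
    else min(config@nPlanted, length(eligible))
    planted <- if (nPlant > 0) sample(eligible, nPlant) else character()

    complexOf <- rep(NA_character_, length(prot))
    names(complexOf) <- prot
    for (cid in names(members)) complexOf[members[[cid]]] <- cid

    wMono <- gaussianProfile(monomerPeak, config@sigmaPeak, nf)
    mixProfile <- function(cid, alpha) {
        if (is.na(cid)) return(wMono)
        wc <- gaussianProfile(peaks[[cid]], config@sigmaPeak, nf)
        alpha * wc + (1 - alpha) * wMono
    }

    abundance <- stats::rlnorm(length(prot), meanlog = log(1e6),
                               sdlog = 0.5)
    heavyW <- t(vapply(complexOf, mixProfile, numeric(nf),
                       alpha = config@alphaRef))
    alphaLight <- config@alphaRef * (1 - config@delta)
    lightW <- t(vapply(seq_along(prot), function(i) {
        cid <- complexOf[i]
        if (!is.na(cid) && cid %in% planted)
            mixProfile(cid, alphaLight)
        else
            mixProfile(cid, config@alphaRef)
    }, numeric(nf)))
    gammaVec <- ifelse(!is.na(complexOf) & complexOf %in% planted,
                       config@gamma, 1)

    noisy <- function(base) {
        m <- base * lognormNoise(length(base), config@noiseCV)
        m[m < config@dropoutThreshold] <- 0
        m
    }
    conc <- stats::runif(nf, 0.8, 1.25)
    asSet <- function(h, l) {
        rownames(h) <- rownames(l) <- prot
        ElutionSet(sweep(h, 2L, conc, `/`), sweep(l, 2L, conc, `/`),
                   concentration = conc)
    }
    expSet <- asSet(noisy(abundance * heavyW),
                    noisy(abundance * gammaVec * lightW))
    ctrlSet <- asSet(noisy(abundance * heavyW),
                     noisy(abundance * heavyW))

    truth <- data.frame(
        complex_id = names(members),
        size = as.integer(sizes),
        peak = as.integer(peaks),
        chr_complex = names(members) %in% chrComplexes,
        planted = names(members) %in% planted,
        delta = ifelse(names(members) %in% planted, config@delta, 0),
        gamma = ifelse(names(members) %in% planted, config@gamma, 1),
        row.names = NULL)
    truth$planted_unstable <- truth$planted &
        (config@delta > 0 | config@gamma < 1)
    list(experiment = expSet, control = ctrlSet, truth = truth)
}

#' Default replacement-line layout
#'
#' Eleven lines, each replacing one chromosome (1 to 11).
#'
#' @param nLines number of lines.
#' @return named list of replaced-chromosome integer vectors.
#' @export
defaultLines <- function(nLines = 11L) {
    stats::setNames(as.list(seq_len(nLines)),
                    sprintf("line%02d", seq_len(nLines)))
}

#' Simulate per-line fold-change matrices with common-response and ESR
#' structure
#'
#' Background log2 fold-changes are Normal(0, nullSd) per gene and line.
#' Planted common-response genes receive +/- \code{effect} in at least
#' \code{minLines} randomly chosen lines.  ESR genes share a latent
#' stress factor: gene loadings times per-line stress intensities are
#' added to their fold-changes, and the same loadings (plus noise)
#' generate the per-condition stress profiles, so a positive ESR
#' correlation is planted.  Adjusted p values are generated consistently
#' with the effect sizes (z = fc / nullSd, two-sided normal p, BH per
#' line).  Genes on a line's replaced chromosome are masked (NA) for that
#' line.
#'
#' @param annot annotation data.frame.
#' @param config A [SimulationConfig-class] (seed and chromosome count).
#' @param lines named list of replaced chromosomes per line.
#' @param nullSd background log2FC standard deviation.
#' @param effect planted common-response effect in log2 units.
#' @param nCommonUp,nCommonDown planted gene counts per direction.
#' @param minLines minimum lines carrying a planted effect.
#' @param nEsr number of ESR genes.
#' @param esrStress mean per-line stress intensity multiplying the ESR
#'   loadings; 0 turns the latent factor off (null transcriptome).
#' @param esrConditions names of the emitted stress-profile columns.
#' @return list with \code{fcTable} (long data.frame), \code{fcMatrix},
#'   \code{lines}, \code{esrProfiles}, \code{truth} (per-gene planted
#'   class and ESR loading).
#' @export
simulateTranscriptome <- function(annot, config, lines = defaultLines(),
                                  nullSd = 0.2, effect = 1.2,
                                  nCommonUp = 30L, nCommonDown = 30L,
                                  minLines = 4L, nEsr = 150L,
                                  esrStress = 0.5,
                                  esrConditions = c("heat", "oxidative",
                                                    "osmotic")) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(stageSeed(config@seed, "transcriptome"))
    genes <- annot$gene_id
    nG <- length(genes)
    nL <- length(lines)
    fc <- matrix(stats::rnorm(nG * nL, 0, nullSd), nG, nL,
                 dimnames = list(genes, names(lines)))

    pick <- sample(genes, nCommonUp + nCommonDown + nEsr)
    upGenes <- pick[seq_len(nCommonUp)]
    downGenes <- pick[nCommonUp + seq_len(nCommonDown)]
    esrGenes <- pick[nCommonUp + nCommonDown + seq_len(nEsr)]

    plantLines <- function() sample(names(lines),
                                    sample(minLines:nL, 1L))
    for (g in upGenes) {
        ls <- plantLines()
        fc[g, ls] <- fc[g, ls] + effect
    }
    for (g in downGenes) {
        ls <- plantLines()
        fc[g, ls] <- fc[g, ls] - effect
    }

    esrLoad <- sample(c(-1, 1), nEsr, replace = TRUE) *
        abs(stats::rnorm(nEsr, 1, 0.3))
    names(esrLoad) <- esrGenes
    stressIntensity <- esrStress * abs(stats::rnorm(nL, 1, 0.4))
    fc[esrGenes, ] <- fc[esrGenes, ] + outer(esrLoad, stressIntensity)
    esrProfiles <- data.frame(gene_id = esrGenes)
    for (cond in esrConditions)
        esrProfiles[[cond]] <- esrLoad + stats::rnorm(nEsr, 0, 0.3)

    padj <- apply(fc, 2, function(col) {
        p <- 2 * stats::pnorm(-abs(col / nullSd))
        stats::p.adjust(p, method = "BH")
    })

    chrOf <- annot$chromosome[match(genes, annot$gene_id)]
    for (ln in names(lines)) {
        mask <- chrOf %in% lines[[ln]]
        fc[mask, ln] <- NA_real_
        padj[mask, ln] <- NA_real_
    }

    fcTable <- data.frame(
        gene_id = rep(genes, times = nL),
        line = rep(names(lines), each = nG),
        log2fc = as.vector(fc),
        padj = as.vector(padj))

    truthClass <- rep("none", nG)
    truthClass[genes %in% upGenes] <- "common_up"
    truthClass[genes %in% downGenes] <- "common_down"
    truthClass[genes %in% esrGenes] <- "esr"
    truth <- data.frame(gene_id = genes, planted_class = truthClass,
                        esr_loading = ifelse(genes %in% esrGenes,
                                             esrLoad[match(genes,
                                                           esrGenes)], 0))
    list(fcTable = fcTable, fcMatrix = fc, lines = lines,
         esrProfiles = esrProfiles, truth = truth)
}

#' Simulate per-line phenotypes coupled to chimeric-complex counts
#'
#' Each line's chimeric-complex count is computed from the simulated
#' compendium and its replaced chromosomes; phenotypes are linear in the
#' count plus Gaussian noise (fitness defect in minutes: a * count +
#' Normal(0, sd)), and growth curves are exponential OD traces whose
#' doubling time carries the same coupling, with 1 percent multiplicative
#' read noise.
#'
#' @param annot,compendium from [simulateAnnotationAndCompendium()].
#' @param config A [SimulationConfig-class] (seed source).
#' @param lines named list of replaced chromosomes per line.
#' @param a phenotype coupling, minutes of fitness defect per complex.
#' @param sd phenotype noise standard deviation in minutes.
#' @param baseDoubling untreated doubling time in minutes.
#' @return list with \code{records} (line, complex_count, fitness_defect,
#'   sporulation_sensitivity, foci_percent), \code{growth} (long
#'   data.frame line, time_min, od), \code{truth} (a, sd, counts).
#' @export
simulatePhenotypes <- function(annot, compendium, config,
                               lines = defaultLines(), a = 3, sd = 10,
                               baseDoubling = 90) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(stageSeed(config@seed, "phenotypes"))
    counts <- vapply(lines, function(repl)
        countComplexesOnChromosomes(compendium, annot, repl), integer(1))
    nL <- length(lines)
    fitness <- a * counts + stats::rnorm(nL, 0, sd)
    sporulation <- pmin(1, pmax(0, 0.04 * counts +
                                   stats::rnorm(nL, 0, 0.05)))
    foci <- pmin(100, pmax(0, 1.5 * counts + stats::rnorm(nL, 0, 2)))
    records <- data.frame(line = names(lines),
                          complex_count = as.integer(counts),
                          fitness_defect = fitness,
                          sporulation_sensitivity = sporulation,
                          foci_percent = foci, row.names = NULL)
    tm <- seq(0, 600, by = 10)
    growth <- do.call(rbind, lapply(names(lines), function(ln) {
        dt <- baseDoubling + a * counts[[ln]]
        od <- 0.05 * exp(log(2) / dt * tm) *
            (1 + stats::rnorm(length(tm), 0, 0.01))
        data.frame(line = ln, time_min = tm, od = od)
    }))
    list(records = records, growth = growth,
         truth = list(a = a, sd = sd, counts = counts))
}

#' Simulate a complete study: annotation, compendium, co-fractionation,
#' transcriptome and phenotypes
#'
#' @param config A [SimulationConfig-class].
#' @param lines named list of replaced chromosomes per line for the
#'   transcriptome/phenotype arms.
#' @param ... passed on to [simulateTranscriptome()].
#' @return named list with every component and its ground truth.
#' @export
simulateStudy <- function(config = simulationConfig(),
                          lines = defaultLines(), ...) {
    ac <- simulateAnnotationAndCompendium(config)
    cf <- simulateCofractionation(ac$annot, ac$compendium, config)
    tr <- simulateTranscriptome(ac$annot, config, lines = lines, ...)
    ph <- simulatePhenotypes(ac$annot, ac$compendium, config,
                             lines = lines)
    list(annot = ac$annot, compendium = ac$compendium,
         cofractionation = cf, transcriptome = tr, phenotypes = ph,
         config = config)
}
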
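#' Run the full analysis pipeline on a simulated or loaded study
#'
#' Orchestrates every stage: concentration correction and normalization of
#' the co-fractionation tables, EPD computation, complex-instability calls
#' (full and excluding replaced-chromosome subunits), grouped box-plot
#' comparisons (Kruskal-Wallis + Dunn), enrichment of replaced-chromosome
#' subunits among unstable complexes, SILAC-ratio abundance tests,
#' common-response classification and ESR correlation, and the
#' phenotype-complex-count correlation.  With an \code{outdir}, per-stage
#' TSVs and a machine-readable JSON summary are written.
#'
#' @param study a study list as returned by [simulateStudy()] (or an
#'   equivalently shaped list of loaded tables).
#' @param nMin minimum quantified subunits per testable complex.
#' @param q FDR level for BH adjustment.
#' @param k minimum lines for common-response status.
#' @param fcThreshold linear fold-change threshold for DE calls.
#' @param outdir optional output directory (created if needed).
#' @return (invisibly) a named list of all stage results plus a
#'   \code{summary} list of headline numbers.
#' @export
runPipeline <- function(study, nMin = 5L, q = 0.05, k = 4L,
                        fcThreshold = 1.5, outdir = NULL) {
    annot <- study$annot
    compendium <- study$compendium
    cfg <- study$config
    log <- character()
    note <- function(...) {
        msg <- paste0(...)
        log <<- c(log, msg)
        message(msg)
    }

    prep <- function(es) {
        es <- concentrationCorrect(es)
        suppressMessages(elutionPatterns(es))
    }
    patExp <- prep(study$cofractionation$experiment)
    patCtrl <- prep(study$cofractionation$control)
    note("elution patterns: ", nrow(patExp), " proteins (experiment), ",
         nrow(patCtrl), " (control); dropped ",
         length(metadata(patExp)$dropped), "/",
         length(metadata(patCtrl)$dropped))
    epdExp <- computeEPD(patExp)
    epdCtrl <- computeEPD(patCtrl)

    calls <- callUnstableComplexes(epdExp, epdCtrl, compendium,
                                   nMin = nMin, q = q)
    callsExcl <- callUnstableExcludingReplaced(
        epdExp, epdCtrl, compendium, annot, cfg@replaced,
        nMin = nMin, q = q)
    note("instability: ", sum(calls$tested), " testable complexes, ",
         sum(calls$unstable), " unstable (",
         sum(callsExcl$unstable), " excluding replaced subunits)")

    quantified <- intersect(epdExp$protein_id, epdCtrl$protein_id)
    groups <- assignProteinGroups(quantified, compendium, annot,
                                  cfg@replaced)
    epdByGroup <- epdExp$epd[match(quantified, epdExp$protein_id)]
    groupTest <- tryCatch({
        kw <- kruskalWallis(epdByGroup, groups)
        dn <- dunnPairwise(epdByGroup, groups)
        list(kruskal = kw, dunn = dn)
    }, error = function(e) {
        note("group test skipped: ", conditionMessage(e))
        NULL
    })

    enrich <- enrichmentFisher(calls, compendium, annot, cfg@replaced)

    ratioExp <- suppressMessages(summarizeRatios(
        concentrationCorrect(study$cofractionation$experiment)))
    ratioCtrl <- suppressMessages(summarizeRatios(
        concentrationCorrect(study$cofractionation$control)))
    abundance <- complexAbundanceTest(ratioExp, ratioCtrl, compendium,
                                      nMin = nMin, q = q)
    note("abundance: ", sum(abundance$unstable),
         " complexes with reduced soluble abundance")

    status <- deStatusMatrix(study$transcriptome$fcTable, annot,
                             study$transcriptome$lines,
                             fcThreshold = fcThreshold, alpha = q)
    common <- commonResponse(status, k = k)
    esr <- esrCorrelation(study$transcriptome$fcMatrix,
                          study$transcriptome$esrProfiles)
    note("transcriptome: ", sum(common$class == "common_up"), " common-up, ",
         sum(common$class == "common_down"), " common-down genes")

    phenoCor <- phenotypeComplexCorrelation(study$phenotypes$records,
                                            "fitness_defect")

    summary <- list(
        n_proteins_quantified = length(quantified),
        n_testable_complexes = sum(calls$tested),
        n_unstable_complexes = sum(calls$unstable),
        n_unstable_excluding_replaced = sum(callsExcl$unstable),
        enrichment_odds_ratio = enrich$odds_ratio,
        enrichment_p = enrich$p,
        n_reduced_abundance_complexes = sum(abundance$unstable),
        n_common_up = sum(common$class == "common_up"),
        n_common_down = sum(common$class == "common_down"),
        esr_rho_median = stats::median(esr$rho),
        phenotype_rho = phenoCor$rho,
        phenotype_p = phenoCor$p)

    result <- list(epd_experiment = epdExp, epd_control = epdCtrl,
                   stability_calls = calls,
                   stability_calls_excluding_replaced = callsExcl,
                   group_test = groupTest, enrichment = enrich,
                   abundance_calls = abundance,
                   common_response = common, esr = esr,
                   phenotype_correlation = phenoCor,
                   summary = summary, log = log)

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeTsv(epdExp, file.path(outdir, "epd_experiment.tsv"))
        writeTsv(epdCtrl, file.path(outdir, "epd_control.tsv"))
        writeTsv(calls, file.path(outdir, "stability_calls.tsv"))
        writeTsv(callsExcl,
                 file.path(outdir,
                           "stability_calls_excluding_replaced.tsv"))
        writeTsv(abundance, file.path(outdir, "abundance_calls.tsv"))
        writeTsv(common, file.path(outdir, "common_response.tsv"))
        writeTsv(esr, file.path(outdir, "esr_correlations.tsv"))
        if (!is.null(groupTest))
            writeTsv(groupTest$dunn, file.path(outdir, "group_tests.tsv"))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        writeLines(log, file.path(outdir, "pipeline.log"))
    }
    invisible(result)
}
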
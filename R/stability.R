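# Shared machinery for complex-level paired tests: complex instability
# (EPD, experimental > control) and complex abundance reduction (log2
# SILAC ratio, experimental < control) run the same paired signed-rank +
# BH pipeline and differ only in the value column and test direction.
complexPairedTest <- function(valExp, valCtrl, compendium,
                              nMin = 5L, q = 0.05,
                              alternative = "greater",
                              valueCol = "epd",
                              excludeProteins = character()) {
    stopifnot(all(c("protein_id", valueCol) %in% names(valExp)),
              all(c("protein_id", valueCol) %in% names(valCtrl)))
    members <- memberList(compendium)
    if (length(excludeProteins))
        members <- lapply(members, setdiff, y = excludeProteins)
    rows <- lapply(names(members), function(cid) {
        prot <- intersect(members[[cid]],
                          intersect(valExp$protein_id, valCtrl$protein_id))
        n <- length(prot)
        if (n < nMin)
            return(data.frame(complex_id = cid, n = n, W = NA_real_,
                              p_raw = NA_real_, tested = FALSE))
        e <- valExp[[valueCol]][match(prot, valExp$protein_id)]
        c0 <- valCtrl[[valueCol]][match(prot, valCtrl$protein_id)]
        wt <- wilcoxonSignedRank(e, c0, alternative = alternative)
        data.frame(complex_id = cid, n = n, W = wt$W, p_raw = wt$p,
                   tested = TRUE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(complex_id = character(), n = integer(),
                          W = numeric(), p_raw = numeric(),
                          tested = logical())
    out$p_adj <- NA_real_
    out$unstable <- FALSE
    if (any(out$tested)) {
        adj <- bhAdjust(out$p_raw[out$tested], q = q)
        out$p_adj[out$tested] <- adj$p_adj
        out$unstable[out$tested] <- adj$significant
    } else {
        warning("no complex has >= ", nMin,
                " subunits quantified in both sets", call. = FALSE)
    }
    rownames(out) <- NULL
    out[order(out$complex_id), , drop = FALSE]
}

#' Call unstable protein complexes from paired EPD tables
#'
#' A complex is testable when at least \code{nMin} of its subunits are
#' quantified in both the experimental and the control set.  For each
#' testable complex the subunit EPD values are compared to the control
#' values with a paired one-sided Wilcoxon signed-rank test (experimental
#' > control), and p values are Benjamini-Hochberg adjusted across all
#' testable complexes of the comparison set.  A complex is called unstable
#' when its adjusted p value is below \code{q}.
#'
#' @param epdExp,epdCtrl data.frames from [computeEPD()] for the
#'   experimental (e.g. Sc/16L) and the control (Sc/Sc) comparison sets.
#' @param compendium A [ComplexCompendium-class].
#' @param nMin minimum quantified subunits per testable complex.
#' @param q FDR level.
#' @return data.frame with one row per complex: \code{complex_id},
#'   \code{n}, \code{W}, \code{p_raw}, \code{p_adj}, \code{unstable},
#'   \code{tested} (untested complexes carry NA statistics).
#' @export
callUnstableComplexes <- function(epdExp, epdCtrl, compendium,
                                  nMin = 5L, q = 0.05) {
    complexPairedTest(epdExp, epdCtrl, compendium, nMin = nMin, q = q,
                      alternative = "greater", valueCol = "epd")
}

#' Instability calls excluding replaced-chromosome subunits
#'
#' Robustness re-analysis: subunits encoded on the replaced chromosomes
#' are removed from every complex before testing, so calls cannot be
#' driven by the foreign proteins themselves.
#'
#' @inheritParams callUnstableComplexes
#' @param annot annotation data.frame ([loadAnnotation()]).
#' @param replaced integer vector of replaced chromosomes.
#' @return As [callUnstableComplexes()]; complexes left with fewer than
#'   \code{nMin} non-replaced subunits become untested.
#' @export
callUnstableExcludingReplaced <- function(epdExp, epdCtrl, compendium,
                                          annot, replaced,
                                          nMin = 5L, q = 0.05) {
    excl <- annot$protein_id[annot$chromosome %in% replaced]
    complexPairedTest(epdExp, epdCtrl, compendium, nMin = nMin, q = q,
                      alternative = "greater", valueCol = "epd",
                      excludeProteins = excl)
}
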
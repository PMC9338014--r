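#' Per-protein log2 SILAC ratios from summed channel intensities
#'
#' ratio = log2(sum of light intensities / sum of heavy intensities) per
#' protein, computed after concentration correction.  With the replacement
#' line in the light channel and the Sc reference in the heavy channel, a
#' negative ratio means reduced soluble abundance in the replacement line.
#' Proteins with a zero total in either channel cannot form a ratio and
#' are excluded (ids in \code{attr(., "excluded")}).
#'
#' @param x An [ElutionSet-class] with unit \code{"intensity"}.
#' @return data.frame with \code{protein_id}, \code{log2_ratio}.
#' @export
summarizeRatios <- function(x) {
    stopifnot(is(x, "ElutionSet"))
    if (identical(metadata(x)$unit, "percent"))
        stop("ratios must be computed from intensities, not patterns")
    h <- rowSums(assay(x, "heavy"))
    l <- rowSums(assay(x, "light"))
    ok <- h > 0 & l > 0
    if (any(!ok))
        message(sum(!ok), " protein(s) excluded from ratios: zero total ",
                "in one channel")
    out <- data.frame(protein_id = rownames(x)[ok],
                      log2_ratio = log2(l[ok] / h[ok]),
                      row.names = NULL)
    attr(out, "excluded") <- rownames(x)[!ok]
    out
}

#' Call complexes with reduced soluble abundance
#'
#' Mirror of [callUnstableComplexes()] on log2 SILAC ratios: for each
#' testable complex the subunit ratios in the experimental set are
#' compared to the control set with a paired one-sided Wilcoxon
#' signed-rank test (experimental < control, i.e. reduced abundance), BH
#' adjusted across testable complexes.
#'
#' @param ratiosExp,ratiosCtrl data.frames from [summarizeRatios()].
#' @inheritParams callUnstableComplexes
#' @return As [callUnstableComplexes()]; the \code{unstable} column here
#'   flags significantly reduced abundance.
#' @export
complexAbundanceTest <- function(ratiosExp, ratiosCtrl, compendium,
                                 nMin = 5L, q = 0.05) {
    complexPairedTest(ratiosExp, ratiosCtrl, compendium, nMin = nMin,
                      q = q, alternative = "less",
                      valueCol = "log2_ratio")
}

#' Protein-transcript correlation per protein group, with pairwise
#' r-to-z comparisons
#'
#' Computes the Spearman correlation between protein-level log2 SILAC
#' ratios and transcript log2 fold-changes within each protein group
#' (chr-complex, non-chr-complex, non-complex), then compares every pair
#' of group correlations with Fisher's r-to-z for independent groups.
#'
#' @param ratios data.frame from [summarizeRatios()].
#' @param transcriptFc data.frame with columns \code{gene_id},
#'   \code{log2fc} for the same line.
#' @param annot annotation data.frame mapping \code{protein_id} to
#'   \code{gene_id} (1:1).
#' @param groups factor from [assignProteinGroups()] aligned with
#'   \code{ratios$protein_id}, or NULL to pass precomputed labels via the
#'   \code{group} column of \code{ratios}.
#' @param minN groups with fewer pairs are skipped with a warning.
#' @return list with \code{by_group} (group, n, rho) and
#'   \code{comparisons} (groupA, groupB, z, p).
#' @export
proteinTranscriptCorrelation <- function(ratios, transcriptFc, annot,
                                         groups = NULL, minN = 4L) {
    if (is.null(groups)) {
        stopifnot("group" %in% names(ratios))
        groups <- ratios$group
    }
    stopifnot(length(groups) == nrow(ratios))
    gene <- annot$gene_id[match(ratios$protein_id, annot$protein_id)]
    fc <- transcriptFc$log2fc[match(gene, transcriptFc$gene_id)]
    keep <- !is.na(gene) & !is.na(fc)
    df <- data.frame(ratio = ratios$log2_ratio[keep], fc = fc[keep],
                     group = droplevels(as.factor(groups[keep])))
    byGroup <- do.call(rbind, lapply(levels(df$group), function(g) {
        sub <- df[df$group == g, ]
        if (nrow(sub) < minN) {
            warning("group '", g, "' has fewer than ", minN,
                    " pairs; skipped", call. = FALSE)
            return(NULL)
        }
        data.frame(group = g, n = nrow(sub),
                   rho = spearmanRho(sub$ratio, sub$fc))
    }))
    comparisons <- NULL
    if (!is.null(byGroup) && nrow(byGroup) >= 2) {
        prs <- utils::combn(seq_len(nrow(byGroup)), 2)
        comparisons <- do.call(rbind, apply(prs, 2, function(ij) {
            a <- byGroup[ij[1], ]; b <- byGroup[ij[2], ]
            # equal correlations need no transform (and |rho| = 1 with
            # rhoA = rhoB would make atanh degenerate)
            rz <- if (a$rho == b$rho) list(z = 0, p = 1)
                  else fisherRToZ(a$rho, a$n, b$rho, b$n)
            data.frame(groupA = a$group, groupB = b$group,
                       z = rz$z, p = rz$p)
        }))
    }
    list(by_group = byGroup, comparisons = comparisons)
}
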
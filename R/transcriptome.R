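#' Classify differential expression from fold-change and adjusted p
#'
#' A gene is \code{up} when its linear fold-change exceeds
#' \code{fcThreshold} (i.e. log2FC > log2(fcThreshold)) with adjusted p <
#' \code{alpha}; \code{down} symmetrically; \code{ns} otherwise.  Missing
#' values yield \code{ns} (the gene cannot be called).
#'
#' @param log2fc numeric vector of log2 fold-changes (line vs parent).
#' @param padj numeric vector of adjusted p values.
#' @param fcThreshold linear fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector in \code{c("up", "down", "ns")}.
#' @export
classifyDE <- function(log2fc, padj, fcThreshold = 1.5, alpha = 0.05) {
    stopifnot(length(log2fc) == length(padj), fcThreshold > 1)
    thr <- log2(fcThreshold)
    out <- rep("ns", length(log2fc))
    ok <- !is.na(log2fc) & !is.na(padj)
    out[ok & log2fc >  thr & padj < alpha] <- "up"
    out[ok & log2fc < -thr & padj < alpha] <- "down"
    out
}

#' Build a DE-status matrix from a long fold-change table
#'
#' Masks genes on each line's replaced chromosomes (they are excluded from
#' that line's DE calls) and classifies the rest with [classifyDE()].
#'
#' @param fcTable data.frame with columns \code{gene_id}, \code{line},
#'   \code{log2fc}, \code{padj}.
#' @param annot annotation data.frame ([loadAnnotation()]).
#' @param replacedByLine named list: replaced chromosome integers per line.
#' @inheritParams classifyDE
#' @return character matrix genes x lines with entries up/down/ns and NA
#'   for masked (gene, line) cells.
#' @export
deStatusMatrix <- function(fcTable, annot, replacedByLine,
                           fcThreshold = 1.5, alpha = 0.05) {
    need <- c("gene_id", "line", "log2fc", "padj")
    stopifnot(all(need %in% names(fcTable)))
    genes <- sort(unique(fcTable$gene_id))
    lines <- sort(unique(fcTable$line))
    status <- matrix(NA_character_, length(genes), length(lines),
                     dimnames = list(genes, lines))
    st <- classifyDE(fcTable$log2fc, fcTable$padj,
                     fcThreshold = fcThreshold, alpha = alpha)
    status[cbind(match(fcTable$gene_id, genes),
                 match(fcTable$line, lines))] <- st
    chrOf <- annot$chromosome[match(genes, annot$gene_id)]
    for (ln in lines) {
        repl <- replacedByLine[[ln]]
        if (is.null(repl)) next
        status[!is.na(chrOf) & chrOf %in% repl, ln] <- NA_character_
    }
    status
}

#' Classify common-response genes across replacement lines
#'
#' A gene is \code{common_up} when it is up in at least \code{k} lines and
#' down in none; \code{common_down} symmetrically.  A gene differentially
#' expressed (either direction) in at least \code{k} lines with both
#' directions present is \code{excluded_bidirectional}.  Everything else
#' is \code{not_common}.  Masked (NA) cells never contribute.
#'
#' @param status character matrix from [deStatusMatrix()].
#' @param k minimum number of lines (default 4).
#' @return data.frame with \code{gene_id}, \code{n_up}, \code{n_down},
#'   \code{class}.
#' @export
commonResponse <- function(status, k = 4L) {
    nUp <- rowSums(status == "up", na.rm = TRUE)
    nDown <- rowSums(status == "down", na.rm = TRUE)
    cls <- rep("not_common", nrow(status))
    cls[nUp + nDown >= k & nUp > 0 & nDown > 0] <- "excluded_bidirectional"
    cls[nUp >= k & nDown == 0] <- "common_up"
    cls[nDown >= k & nUp == 0] <- "common_down"
    data.frame(gene_id = rownames(status), n_up = nUp, n_down = nDown,
               class = cls, row.names = NULL)
}

#' Correlate the median replacement-line response of ESR genes with
#' canonical stress profiles
#'
#' For each stress condition, computes the Spearman correlation between
#' the median log2 fold-change of the environmental-stress-response (ESR)
#' genes across all replacement lines and the genes' log2 response under
#' that stress.
#'
#' @param fcMatrix numeric matrix genes x lines of log2 fold-changes (NA
#'   allowed for masked cells).
#' @param esrProfiles data.frame with \code{gene_id} plus one numeric
#'   column per stress condition.
#' @param minShared minimum number of ESR genes shared with the matrix.
#' @return data.frame with \code{condition}, \code{n}, \code{rho}.
#' @export
esrCorrelation <- function(fcMatrix, esrProfiles, minShared = 10L) {
    stopifnot("gene_id" %in% names(esrProfiles))
    shared <- intersect(rownames(fcMatrix), esrProfiles$gene_id)
    if (length(shared) < minShared)
        stop("only ", length(shared), " ESR genes shared; need >= ",
             minShared)
    med <- apply(fcMatrix[shared, , drop = FALSE], 1, stats::median,
                 na.rm = TRUE)
    conds <- setdiff(names(esrProfiles), "gene_id")
    do.call(rbind, lapply(conds, function(cd) {
        prof <- esrProfiles[[cd]][match(shared, esrProfiles$gene_id)]
        data.frame(condition = cd, n = length(shared),
                   rho = spearmanRho(med, prof))
    }))
}
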
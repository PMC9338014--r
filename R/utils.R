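readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# small Bron-Kerbosch on an adjacency matrix; groups are few (<10)
maxCliques <- function(adj) {
    n <- nrow(adj)
    out <- list()
    bk <- function(R, P, X) {
        if (!length(P) && !length(X)) {
            out[[length(out) + 1L]] <<- sort(R)
            return(invisible())
        }
        for (v in P) {
            nb <- setdiff(which(adj[v, ]), v)
            bk(c(R, v), intersect(P, nb), intersect(X, nb))
            P <- setdiff(P, v)
            X <- c(X, v)
        }
    }
    bk(integer(), seq_len(n), integer())
    out
}

#' Compact-letter display from a pairwise p-value matrix
#'
#' Groups whose pairwise comparison is not significant share a letter
#' (letters correspond to maximal cliques of the non-significant-pair
#' graph), mirroring the annotation style of grouped box plots.
#'
#' @param pmat symmetric matrix of adjusted pairwise p values with group
#'   names on both dimensions.
#' @param alpha significance threshold.
#' @return named character vector of letter strings per group.
#' @export
groupLetters <- function(pmat, alpha = 0.05) {
    stopifnot(is.matrix(pmat), nrow(pmat) == ncol(pmat))
    adj <- pmat > alpha
    diag(adj) <- TRUE
    cl <- maxCliques(adj)
    lets <- vapply(seq_len(nrow(pmat)), function(i) {
        paste(letters[which(vapply(cl, function(cq) i %in% cq, logical(1)))],
              collapse = "")
    }, character(1))
    stats::setNames(lets, rownames(pmat))
}
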
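#' Construct a ComplexCompendium
#'
#' @param membership data.frame with columns \code{complex_id},
#'   \code{protein_id}; duplicate membership rows are collapsed.
#' @param complexName optional named character vector of display names.
#' @param provenance optional data.frame with columns \code{complex_id},
#'   \code{flag}, \code{reason}.
#' @return A [ComplexCompendium-class] object.
#' @export
ComplexCompendium <- function(membership,
                              complexName = character(),
                              provenance = NULL) {
    stopifnot(is.data.frame(membership))
    if (!all(c("complex_id", "protein_id") %in% names(membership)))
        stop("membership requires columns 'complex_id' and 'protein_id'")
    m <- unique(membership[, c("complex_id", "protein_id")])
    m$complex_id <- as.character(m$complex_id)
    m$protein_id <- as.character(m$protein_id)
    rownames(m) <- NULL
    if (is.null(provenance))
        provenance <- data.frame(complex_id = character(),
                                 flag = character(), reason = character())
    new("ComplexCompendium", membership = m,
        complexName = complexName, provenance = provenance)
}

#' Compendium accessors
#'
#' \code{nComplexes} and \code{nSubunits} count complexes and distinct
#' subunit proteins; \code{complexIds} and \code{subunitIds} return their
#' identifiers; \code{memberList} returns the membership as a named list of
#' protein-id character vectors.
#'
#' @param x A [ComplexCompendium-class].
#' @return Counts, id vectors, or a named list.
#' @name nComplexes
#' @aliases nSubunits complexIds subunitIds memberList
NULL

#' @rdname nComplexes
setMethod("nComplexes", "ComplexCompendium",
    function(x) length(unique(x@membership$complex_id)))

#' @rdname nComplexes
setMethod("nSubunits", "ComplexCompendium",
    function(x) length(unique(x@membership$protein_id)))

#' @rdname nComplexes
setMethod("complexIds", "ComplexCompendium",
    function(x) unique(x@membership$complex_id))

#' @rdname nComplexes
setMethod("subunitIds", "ComplexCompendium",
    function(x) unique(x@membership$protein_id))

#' @rdname nComplexes
setMethod("memberList", "ComplexCompendium", function(x) {
    split(x@membership$protein_id, x@membership$complex_id)
})

setMethod("show", "ComplexCompendium", function(object) {
    cat("ComplexCompendium with", nComplexes(object), "complexes and",
        nSubunits(object), "distinct subunits\n")
    sz <- table(object@membership$complex_id)
    if (length(sz))
        cat("complex sizes: min", min(sz), "/ median", stats::median(sz),
            "/ max", max(sz), "\n")
    if (nrow(object@provenance))
        cat("provenance flags:",
            paste(names(table(object@provenance$flag)),
                  table(object@provenance$flag), collapse = ", "), "\n")
})

#' Load a protein-complex compendium from a TSV file
#'
#' Reads a curated complex-membership table (one row per membership) into a
#' [ComplexCompendium-class].  Duplicate membership rows are collapsed.
#' Complexes with fewer than two members are retained but flagged with a
#' warning; they are excluded from chromosome counting by downstream
#' operations.
#'
#' @param path TSV with header columns \code{complex_id}, \code{protein_id}
#'   and optionally \code{name}, \code{provenance_flag}, \code{reason}.
#' @param quiet suppress the summary message.
#' @return A [ComplexCompendium-class].
#' @export
loadCompendium <- function(path, quiet = FALSE) {
    tab <- readTsv(path)
    if (!all(c("complex_id", "protein_id") %in% names(tab)))
        stop("compendium file must have columns 'complex_id', 'protein_id'")
    nm <- character()
    if ("name" %in% names(tab)) {
        u <- unique(tab[, c("complex_id", "name")])
        nm <- stats::setNames(as.character(u$name), u$complex_id)
    }
    pv <- NULL
    if ("provenance_flag" %in% names(tab)) {
        u <- unique(data.frame(
            complex_id = tab$complex_id,
            flag = tab$provenance_flag,
            reason = if ("reason" %in% names(tab)) tab$reason else ""))
        pv <- u
    }
    cc <- ComplexCompendium(tab, complexName = nm, provenance = pv)
    sz <- table(cc@membership$complex_id)
    small <- names(sz)[sz < 2]
    if (length(small))
        warning(length(small), " complex(es) with <2 members retained but ",
                "flagged: ", paste(utils::head(small, 5), collapse = ", "),
                call. = FALSE)
    if (!quiet)
        message("loaded compendium: ", nComplexes(cc), " complexes, ",
                nSubunits(cc), " distinct subunits")
    cc
}

#' Load a gene-to-chromosome annotation from a TSV file
#'
#' @param path TSV with header columns \code{gene_id}, \code{protein_id},
#'   \code{chromosome} (Arabic 1-16 or Roman numerals, converted on load)
#'   and optionally \code{length_bp}.
#' @return data.frame with integer \code{chromosome}.
#' @export
loadAnnotation <- function(path) {
    tab <- readTsv(path)
    need <- c("gene_id", "protein_id", "chromosome")
    if (!all(need %in% names(tab)))
        stop("annotation file must have columns ",
             paste(need, collapse = ", "))
    tab$chromosome <- chromosomeToInt(tab$chromosome)
    validateAnnotation(tab)
    tab
}

validateAnnotation <- function(annot) {
    if (anyDuplicated(annot$gene_id))
        stop("gene_id values must be unique")
    if (anyDuplicated(annot$protein_id))
        stop("protein_id values must be unique (1:1 gene-protein mapping)")
    if (any(annot$chromosome < 1 | annot$chromosome > 16))
        stop("chromosome must be in 1..16")
    invisible(annot)
}

#' Convert chromosome labels to integers
#'
#' Accepts Arabic integers, Roman numerals (\code{IV}, \code{chrXVI}) or a
#' \code{chr} prefix on either.
#'
#' @param x character or numeric vector.
#' @return integer vector.
#' @export
chromosomeToInt <- function(x) {
    x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
    out <- suppressWarnings(as.integer(x))
    rom <- is.na(out) & grepl("^[IVXLCDM]+$", toupper(x))
    out[rom] <- as.integer(utils::as.roman(toupper(x[rom])))
    if (any(is.na(out)))
        stop("unparseable chromosome labels: ",
             paste(unique(x[is.na(out)]), collapse = ", "))
    out
}

# Membership restricted to complexes with >= minSize members, all annotated.
annotatedMembership <- function(compendium, annot, minSize = 2L) {
    m <- compendium@membership
    missing <- setdiff(m$protein_id, annot$protein_id)
    if (length(missing))
        stop("unannotated compendium members: ",
             paste(utils::head(missing, 10), collapse = ", "),
             if (length(missing) > 10) " ..." else "")
    sz <- table(m$complex_id)
    keep <- names(sz)[sz >= minSize]
    m <- m[m$complex_id %in% keep, , drop = FALSE]
    m$chromosome <- annot$chromosome[match(m$protein_id, annot$protein_id)]
    m
}

#' Count complexes with subunits on replaced chromosomes
#'
#' Returns the number of unique complexes with at least one member encoded
#' on any of the replaced chromosomes.  Complexes with fewer than two
#' members are excluded (not complexes for interaction purposes).
#'
#' @param compendium A [ComplexCompendium-class].
#' @param annot annotation data.frame as from [loadAnnotation()].
#' @param replaced integer vector of replaced chromosomes.
#' @return integer count.
#' @export
countComplexesOnChromosomes <- function(compendium, annot, replaced) {
    m <- annotatedMembership(compendium, annot)
    length(unique(m$complex_id[m$chromosome %in% replaced]))
}

#' Fraction of replaced-chromosome proteins that are complex subunits
#'
#' Computes (# distinct annotated proteins on the replaced chromosomes that
#' are subunits of some complex) / (# all annotated proteins on the
#' replaced chromosomes).
#'
#' @inheritParams countComplexesOnChromosomes
#' @return fraction in [0, 1].
#' @export
complexProteinRatio <- function(compendium, annot, replaced) {
    onChr <- unique(annot$protein_id[annot$chromosome %in% replaced])
    if (!length(onChr))
        stop("no annotated proteins on the replaced chromosome(s)")
    m <- annotatedMembership(compendium, annot)
    length(intersect(onChr, unique(m$protein_id))) / length(onChr)
}

#' Assign proteins to chr-complex / non-chr-complex / non-complex groups
#'
#' A protein is \code{chr_complex} if it belongs to at least one complex
#' that has any subunit encoded on a replaced chromosome,
#' \code{non_chr_complex} if it belongs only to complexes without such
#' subunits, and \code{non_complex} otherwise.  Proteins that are members
#' of both kinds of complexes take the label chosen by \code{bothRule}
#' (default \code{chr_complex}: any membership in a chimeric-candidate
#' complex exposes the protein to it).
#'
#' @param proteinIds character vector of quantified proteins.
#' @inheritParams countComplexesOnChromosomes
#' @param bothRule label for proteins in both kinds of complexes.
#' @return factor with levels \code{non_complex}, \code{chr_complex},
#'   \code{non_chr_complex}.
#' @export
assignProteinGroups <- function(proteinIds, compendium, annot, replaced,
                                bothRule = c("chr_complex",
                                             "non_chr_complex")) {
    bothRule <- match.arg(bothRule)
    m <- annotatedMembership(compendium, annot)
    chrComplexes <- unique(m$complex_id[m$chromosome %in% replaced])
    inChr <- unique(m$protein_id[m$complex_id %in% chrComplexes])
    inNonChr <- unique(m$protein_id[!(m$complex_id %in% chrComplexes)])
    lab <- rep("non_complex", length(proteinIds))
    isChr <- proteinIds %in% inChr
    isNon <- proteinIds %in% inNonChr
    lab[isNon] <- "non_chr_complex"
    lab[isChr] <- "chr_complex"
    if (bothRule == "non_chr_complex")
        lab[isChr & isNon] <- "non_chr_complex"
    factor(lab, levels = c("non_complex", "chr_complex", "non_chr_complex"))
}
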
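#' Construct an ElutionSet from heavy/light intensity matrices
#'
#' @param heavy,light numeric matrices (proteins x fractions) of
#'   non-negative intensities with protein ids as row names.  Columns are
#'   SEC fractions 1..F in order.
#' @param concentration optional numeric vector of per-fraction peptide
#'   concentrations (length F, all > 0).
#' @param unit \code{"intensity"} (default) or \code{"percent"}.
#' @return An [ElutionSet-class].
#' @export
ElutionSet <- function(heavy, light, concentration = NULL,
                       unit = c("intensity", "percent")) {
    unit <- match.arg(unit)
    stopifnot(is.matrix(heavy), is.matrix(light),
              identical(dim(heavy), dim(light)),
              identical(rownames(heavy), rownames(light)))
    f <- ncol(heavy)
    cd <- DataFrame(fraction = seq_len(f))
    if (!is.null(concentration)) {
        stopifnot(length(concentration) == f)
        if (any(concentration <= 0))
            stop("peptide concentrations must be positive")
        cd$concentration <- as.numeric(concentration)
    }
    colnames(heavy) <- colnames(light) <- paste0("F", seq_len(f))
    se <- SummarizedExperiment(
        assays = list(heavy = heavy, light = light), colData = cd)
    metadata(se)$unit <- unit
    new("ElutionSet", se)
}

setMethod("show", "ElutionSet", function(object) {
    cat("ElutionSet:", nrow(object), "proteins x", ncol(object),
        "fractions (unit:", metadata(object)$unit, ")\n")
    cat("concentration:",
        if ("concentration" %in% names(colData(object))) "stored"
        else "absent", "\n")
})

#' Read a tidy per-fraction SILAC intensity table
#'
#' Reads the long-format dialect \code{protein_id, channel, fraction,
#' intensity} (one row per observed value).  Fraction/channel combinations
#' absent from the file are treated as zero intensity, matching
#' MaxQuant-style outputs that omit undetected fractions.
#'
#' @param path intensity TSV.
#' @param concPath optional concentration TSV with columns \code{fraction},
#'   \code{concentration}.
#' @param nFractions total number of fractions; defaults to the maximum
#'   fraction index present.
#' @return An [ElutionSet-class].
#' @export
readIntensityTable <- function(path, concPath = NULL, nFractions = NULL) {
    tab <- readTsv(path)
    need <- c("protein_id", "channel", "fraction", "intensity")
    if (!all(need %in% names(tab)))
        stop("intensity file must have columns ", paste(need, collapse = ", "))
    if (!all(tab$channel %in% c("heavy", "light")))
        stop("channel must be 'heavy' or 'light'")
    if (any(tab$intensity < 0)) stop("negative intensities")
    f <- if (is.null(nFractions)) max(tab$fraction) else nFractions
    prots <- sort(unique(tab$protein_id))
    mk <- function(ch) {
        sub <- tab[tab$channel == ch, ]
        m <- matrix(0, length(prots), f,
                    dimnames = list(prots, NULL))
        m[cbind(match(sub$protein_id, prots), sub$fraction)] <- sub$intensity
        m
    }
    conc <- NULL
    if (!is.null(concPath)) {
        ct <- readTsv(concPath)
        if (!all(c("fraction", "concentration") %in% names(ct)))
            stop("concentration file must have columns fraction, concentration")
        conc <- ct$concentration[match(seq_len(f), ct$fraction)]
        if (anyNA(conc))
            stop("missing concentration for fraction(s) ",
                 paste(which(is.na(conc)), collapse = ", "))
    }
    ElutionSet(mk("heavy"), mk("light"), concentration = conc)
}

#' Pool consecutive SEC fractions
#'
#' Sums every \code{by} sequential fractions into one (the acquisition
#' pools 81 raw fractions into 27 by threes).  Per-protein, per-channel
#' totals are conserved exactly.  Stored concentrations are averaged within
#' each pooled triple.
#'
#' @param x An [ElutionSet-class] with F divisible by \code{by}.
#' @param by pooling factor (default 3).
#' @return An [ElutionSet-class] with F/\code{by} fractions.
#' @rdname poolFractions
#' @export
setMethod("poolFractions", "ElutionSet", function(x, by = 3L) {
    f <- ncol(x)
    if (f %% by != 0L)
        stop("number of fractions (", f, ") not divisible by ", by)
    if (identical(metadata(x)$unit, "percent"))
        stop("pool before normalization, not after")
    grp <- rep(seq_len(f %/% by), each = by)
    poolMat <- function(m)
        t(rowsum(t(m), grp, reorder = TRUE))
    conc <- NULL
    if ("concentration" %in% names(colData(x)))
        conc <- as.numeric(tapply(colData(x)$concentration, grp, mean))
    ElutionSet(poolMat(assay(x, "heavy")), poolMat(assay(x, "light")),
               concentration = conc)
})

#' Correct intensities by per-fraction peptide concentration
#'
#' Multiplies each fraction's intensities by that fraction's peptide
#' concentration, in both channels.
#'
#' @param x An [ElutionSet-class].
#' @param concentration numeric vector of length F; if NULL the
#'   concentrations stored in \code{colData(x)} are used.
#' @return A corrected [ElutionSet-class] (concentration column removed:
#'   it has been applied).
#' @rdname concentrationCorrect
#' @export
setMethod("concentrationCorrect", "ElutionSet",
    function(x, concentration = NULL) {
    if (is.null(concentration)) {
        if (!"concentration" %in% names(colData(x)))
            stop("no concentration supplied or stored")
        concentration <- colData(x)$concentration
    }
    if (length(concentration) != ncol(x))
        stop("concentration length must equal the number of fractions")
    if (any(is.na(concentration) | concentration <= 0))
        stop("concentrations must be positive for every fraction")
    scale <- function(m) sweep(m, 2L, concentration, `*`)
    ElutionSet(scale(assay(x, "heavy")), scale(assay(x, "light")))
})

#' Normalize intensities into elution patterns
#'
#' Divides each protein's per-channel intensities by that channel's total
#' and converts to percentages, so every (protein, channel) pattern sums
#' to 100.  Proteins whose heavy or light channel has zero total -- or is
#' detected in fewer than \code{minFractions} fractions -- cannot form a
#' pattern pair and are dropped with a message listing the count.
#'
#' @param x An [ElutionSet-class] with unit \code{"intensity"}.
#' @param minFractions minimum number of nonzero fractions per channel.
#' @return An [ElutionSet-class] with unit \code{"percent"}; the dropped
#'   protein ids are available as \code{metadata(.)$dropped}.
#' @rdname elutionPatterns
#' @export
setMethod("elutionPatterns", "ElutionSet", function(x, minFractions = 1L) {
    h <- assay(x, "heavy"); l <- assay(x, "light")
    ok <- rowSums(h > 0) >= minFractions & rowSums(l > 0) >= minFractions
    if (any(!ok))
        message(sum(!ok), " protein(s) dropped: undetected or below ",
                minFractions, " fraction(s) in one channel")
    h <- h[ok, , drop = FALSE]; l <- l[ok, , drop = FALSE]
    pct <- function(m) 100 * m / rowSums(m)
    es <- ElutionSet(pct(h), pct(l), unit = "percent")
    metadata(es)$dropped <- rownames(x)[!ok]
    es
})

#' Elution pattern difference (EPD)
#'
#' The EPD of a protein is the L1 distance between its heavy- and
#' light-channel elution patterns: EPD = sum over fractions of
#' |heavy% - light%|.  It ranges from 0 (identical co-elution) to 200
#' (disjoint elution), is symmetric in the channels, and is invariant to
#' rescaling either channel's raw intensities.
#'
#' @param x An [ElutionSet-class] with unit \code{"percent"} (see
#'   [elutionPatterns()]).
#' @return data.frame with columns \code{protein_id}, \code{epd}.
#' @seealso [epdDifferences()] for the signed per-fraction differences.
#' @export
computeEPD <- function(x) {
    d <- epdDifferences(x)
    data.frame(protein_id = rownames(d), epd = rowSums(abs(d)),
               row.names = NULL)
}

#' Signed per-fraction pattern differences
#'
#' @param x An [ElutionSet-class] with unit \code{"percent"}.
#' @return matrix (proteins x fractions) of heavy% - light%.
#' @export
epdDifferences <- function(x) {
    stopifnot(is(x, "ElutionSet"))
    if (!identical(metadata(x)$unit, "percent"))
        stop("computeEPD expects normalized patterns; run elutionPatterns()")
    assay(x, "heavy") - assay(x, "light")
}

#' EPD table restricted to proteins not encoded on replaced chromosomes
#'
#' Robustness re-analysis input: proteins encoded on the replaced
#' chromosomes are removed so that any species-specific elution behaviour
#' of the foreign proteins themselves cannot drive complex-level calls.
#'
#' @param epdTable data.frame from [computeEPD()].
#' @param annot annotation data.frame ([loadAnnotation()]).
#' @param replaced integer vector of replaced chromosomes.
#' @return filtered EPD data.frame.
#' @export
epdExcludingReplaced <- function(epdTable, annot, replaced) {
    onChr <- annot$protein_id[annot$chromosome %in% replaced]
    epdTable[!(epdTable$protein_id %in% onChr), , drop = FALSE]
}
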
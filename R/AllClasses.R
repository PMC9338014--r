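#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ComplexCompendium: a curated protein-complex membership table
#'
#' Holds the complex-to-subunit membership of a curated compendium of
#' protein complexes (one row per membership), optional complex names and a
#' per-complex provenance flag recording how the record relates to the
#' source compendium (\code{kept}, \code{modified}, or \code{removed} with a
#' reason).
#'
#' @slot membership data.frame with columns \code{complex_id},
#'   \code{protein_id}; duplicate rows are not allowed.
#' @slot complexName named character vector of display names, named by
#'   \code{complex_id} (may be empty).
#' @slot provenance data.frame with columns \code{complex_id}, \code{flag}
#'   (\code{kept}/\code{modified}/\code{removed}) and \code{reason}.
#'
#' @seealso [loadCompendium()], [nComplexes()], [memberList()]
#' @export
setClass("ComplexCompendium",
    slots = c(
        membership  = "data.frame",
        complexName = "character",
        provenance  = "data.frame"
    ),
    prototype = prototype(
        membership  = data.frame(complex_id = character(),
                                 protein_id = character()),
        complexName = character(),
        provenance  = data.frame(complex_id = character(),
                                 flag = character(), reason = character())
    )
)

setValidity("ComplexCompendium", function(object) {
    m <- object@membership
    msgs <- character()
    if (!all(c("complex_id", "protein_id") %in% names(m)))
        msgs <- c(msgs, "membership must have columns complex_id, protein_id")
    else {
        if (anyDuplicated(m[, c("complex_id", "protein_id")]))
            msgs <- c(msgs, "duplicate (complex_id, protein_id) rows")
        if (any(is.na(m$complex_id)) || any(is.na(m$protein_id)))
            msgs <- c(msgs, "NA in membership ids")
    }
    pv <- object@provenance
    if (nrow(pv)) {
        bad <- setdiff(unique(pv$flag), c("kept", "modified", "removed"))
        if (length(bad))
            msgs <- c(msgs, paste0("unknown provenance flag: ",
                                   paste(bad, collapse = ", ")))
        rm_no_reason <- pv$flag == "removed" &
            (is.na(pv$reason) | !nzchar(pv$reason))
        if (any(rm_no_reason))
            msgs <- c(msgs, "removed records must carry a reason")
    }
    if (length(msgs)) msgs else TRUE
})

#' ElutionSet: per-fraction SILAC intensities or elution patterns
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] with two assays,
#' \code{heavy} and \code{light}, holding one protein per row and one SEC
#' fraction per column.  \code{colData} carries the 1-based fraction index
#' and, when available, the per-fraction peptide concentration shared by
#' all proteins.  \code{metadata(x)$unit} is \code{"intensity"} for raw or
#' corrected intensities and \code{"percent"} after [elutionPatterns()]
#' normalization (rows then sum to 100 per channel).
#'
#' @seealso [ElutionSet()], [poolFractions()], [concentrationCorrect()],
#'   [elutionPatterns()], [computeEPD()]
#' @export
setClass("ElutionSet", contains = "SummarizedExperiment")

setValidity("ElutionSet", function(object) {
    msgs <- character()
    if (!all(c("heavy", "light") %in% assayNames(object)))
        msgs <- c(msgs, "assays 'heavy' and 'light' are required")
    if (!"fraction" %in% names(colData(object)))
        msgs <- c(msgs, "colData must contain a 'fraction' column")
    else {
        fr <- colData(object)$fraction
        if (!identical(as.integer(fr), seq_len(ncol(object))))
            msgs <- c(msgs, "fractions must be contiguous 1..F")
    }
    unit <- metadata(object)$unit
    if (!is.null(unit) && !unit %in% c("intensity", "percent"))
        msgs <- c(msgs, "metadata unit must be 'intensity' or 'percent'")
    for (a in intersect(c("heavy", "light"), assayNames(object))) {
        v <- assay(object, a)
        if (any(v < 0, na.rm = TRUE))
            msgs <- c(msgs, paste0("negative values in assay '", a, "'"))
    }
    if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module with validated defaults.
#' The defaults describe the simulated study conditions: 27 SEC fractions,
#' a reference assembled fraction of 0.9, log-normal multiplicative noise
#' with CV 0.2, and chromosome 16 as the replaced chromosome.
#'
#' @slot seed integer; all generator randomness flows from it.
#' @slot nGenes,nChromosomes,nComplexes integers sizing the genome.
#' @slot sizeMin,sizeMax,sizeGeomP complex-size distribution: size =
#'   sizeMin + Geometric(sizeGeomP), truncated at sizeMax.
#' @slot nFractions number of SEC fractions after pooling (27).
#' @slot alphaRef assembled fraction of complex subunits in the reference
#'   channel, in [0,1].
#' @slot delta planted destabilization effect in [0,1]; the light-channel
#'   assembled fraction of a planted complex is alphaRef * (1 - delta).
#' @slot gamma planted degradation factor in (0,1]; light-channel totals of
#'   planted complexes are scaled by gamma.
#' @slot sigmaPeak Gaussian elution-peak spread in fractions.
#' @slot noiseCV coefficient of variation of the multiplicative log-normal
#'   intensity noise.
#' @slot dropoutThreshold intensities below this are set to 0.
#' @slot replaced integer vector of replaced chromosomes.
#' @slot plantFraction fraction of chr-complexes planted unstable (used
#'   when nPlanted is NA).
#' @slot nPlanted exact number of complexes to plant (NA = use
#'   plantFraction).
#' @slot plantMinSize only complexes with at least this many subunits are
#'   eligible for planting.
#'
#' @seealso [simulationConfig()], [simulateStudy()]
#' @export
setClass("SimulationConfig",
    slots = c(
        seed             = "integer",
        nGenes           = "integer",
        nChromosomes     = "integer",
        nComplexes       = "integer",
        sizeMin          = "integer",
        sizeMax          = "integer",
        sizeGeomP        = "numeric",
        nFractions       = "integer",
        alphaRef         = "numeric",
        delta            = "numeric",
        gamma            = "numeric",
        sigmaPeak        = "numeric",
        noiseCV          = "numeric",
        dropoutThreshold = "numeric",
        replaced         = "integer",
        plantFraction    = "numeric",
        nPlanted         = "integer",
        plantMinSize     = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    inUnit <- function(x) x >= 0 && x <= 1
    if (!inUnit(object@alphaRef)) msgs <- c(msgs, "alphaRef must be in [0,1]")
    if (!inUnit(object@delta))    msgs <- c(msgs, "delta must be in [0,1]")
    if (object@gamma <= 0 || object@gamma > 1)
        msgs <- c(msgs, "gamma must be in (0,1]")
    if (!inUnit(object@plantFraction))
        msgs <- c(msgs, "plantFraction must be in [0,1]")
    if (!inUnit(object@sizeGeomP)) msgs <- c(msgs, "sizeGeomP must be in [0,1]")
    if (object@sizeMin < 2) msgs <- c(msgs, "sizeMin must be >= 2")
    if (object@sizeMax < object@sizeMin)
        msgs <- c(msgs, "sizeMax must be >= sizeMin")
    if (object@noiseCV < 0) msgs <- c(msgs, "noiseCV must be >= 0")
    if (object@sigmaPeak <= 0) msgs <- c(msgs, "sigmaPeak must be > 0")
    if (as.double(object@nComplexes) * object@sizeMax > object@nGenes)
        msgs <- c(msgs, "nComplexes * sizeMax exceeds nGenes")
    if (any(object@replaced < 1 | object@replaced > object@nChromosomes))
        msgs <- c(msgs, "replaced chromosomes outside 1..nChromosomes")
    if (length(msgs)) msgs else TRUE
})
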
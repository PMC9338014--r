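#' @rdname nComplexes
#' @export
setGeneric("nComplexes", function(x) standardGeneric("nComplexes"))

#' @rdname nComplexes
#' @export
setGeneric("nSubunits", function(x) standardGeneric("nSubunits"))

#' @rdname nComplexes
#' @export
setGeneric("complexIds", function(x) standardGeneric("complexIds"))

#' @rdname nComplexes
#' @export
setGeneric("subunitIds", function(x) standardGeneric("subunitIds"))

#' @rdname nComplexes
#' @export
setGeneric("memberList", function(x) standardGeneric("memberList"))

#' @rdname poolFractions
#' @export
setGeneric("poolFractions", function(x, by = 3L) standardGeneric("poolFractions"))

#' @rdname concentrationCorrect
#' @export
setGeneric("concentrationCorrect",
    function(x, concentration = NULL) standardGeneric("concentrationCorrect"))

#' @rdname elutionPatterns
#' @export
setGeneric("elutionPatterns",
    function(x, minFractions = 1L) standardGeneric("elutionPatterns"))
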
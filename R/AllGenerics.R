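#' @rdname GeneModelSet-class
#' @param x,object A `GeneModelSet`.
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("nExons", function(x) standardGeneric("nExons"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneChroms", function(x) standardGeneric("geneChroms"))

#' @rdname ReadPairSet-class
#' @param x,object A `ReadPairSet`.
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' @rdname ReadPairSet-class
#' @export
setGeneric("parseLog", function(x) standardGeneric("parseLog"))

#' @rdname SignatureCounts-class
#' @param x,object A `SignatureCounts`.
#' @export
setGeneric("sigCounts", function(x) standardGeneric("sigCounts"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("sigTotal", function(x) standardGeneric("sigTotal"))

#' @rdname PhaseCall-class
#' @param x,object A `PhaseCall`.
#' @export
setGeneric("phaseVerdict", function(x) standardGeneric("phaseVerdict"))

#' @rdname PhaseCall-class
#' @export
setGeneric("phaseCounts", function(x) standardGeneric("phaseCounts"))
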
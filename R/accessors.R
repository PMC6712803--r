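## Accessors and show() methods; slots are never touched outside this file
## and the constructors.

#' @rdname GeneModelSet-class
#' @aliases exons,GeneModelSet-method
#' @export
setMethod("exons", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneSymbols", "GeneModelSet", function(x) names(x@exons))

#' @rdname GeneModelSet-class
#' @export
setMethod("nExons", "GeneModelSet",
          function(x) setNames(S4Vectors::elementNROWS(x@exons),
                               names(x@exons)))

#' @rdname GeneModelSet-class
#' @export
setMethod("geneChroms", "GeneModelSet", function(x) {
    setNames(vapply(x@exons,
                    function(g) as.character(seqnames(g)[1L]), ""),
             names(x@exons))
})

#' @rdname GeneModelSet-class
#' @export
setMethod("introns", "GeneModelSet", function(x) {
    endoapply2 <- function(f) GRangesList(lapply(x@exons, f))
    endoapply2(function(g) {
        n <- length(g)
        if (n < 2L)
            return(GRanges(seqnames = character(0), ranges = IRanges()))
        GRanges(seqnames(g)[1L],
                IRanges(start = end(g)[-n] + 1L, end = start(g)[-1L] - 1L),
                strand = strand(g)[1L])
    })
})

#' @rdname GeneModelSet-class
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@exons))

#' @rdname GeneModelSet-class
#' @param i Gene symbol(s) or indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "GeneModelSet", function(x, i, j, ..., drop = FALSE) {
    new("GeneModelSet", exons = x@exons[i])
})

setMethod("show", "GeneModelSet", function(object) {
    n <- nExons(object)
    cat("GeneModelSet with", length(object), "genes on",
        length(unique(geneChroms(object))), "chromosome(s)\n")
    cat("  exons per gene:", min(n), "-", max(n),
        sprintf("(%d intron-bearing)", sum(n >= 2L)), "\n")
})

#' @rdname ReadPairSet-class
#' @export
setMethod("pairData", "ReadPairSet", function(x) x@pairs)

#' @rdname ReadPairSet-class
#' @export
setMethod("parseLog", "ReadPairSet", function(x) x@log)

#' @rdname ReadPairSet-class
#' @export
setMethod("length", "ReadPairSet", function(x) nrow(x@pairs))

setMethod("show", "ReadPairSet", function(object) {
    p <- object@pairs
    cat("ReadPairSet with", nrow(p), "pairs from",
        length(unique(p$sample_id)), "sample(s)\n")
    if (nrow(p) > 0L)
        cat("  ostensible template length:", min(p$tlen), "-", max(p$tlen),
            "bp (median", stats::median(p$tlen), ")\n")
})

setMethod("show", "DetectionParams", function(object) {
    cat("DetectionParams: both-mate MAPQ >=", object@min_mapq,
        "; tlen >=", object@min_tlen, "bp;\n  >=",
        object@min_supported_exons, "supported exons at >=",
        object@min_reads_per_exon, "read ends each; relic recurrence >=",
        object@recurrence_fraction, "\n")
})

#' @rdname SignatureCounts-class
#' @export
setMethod("sigCounts", "SignatureCounts", function(x) x@counts)

#' @rdname SignatureCounts-class
#' @export
setMethod("sigTotal", "SignatureCounts", function(x) x@total)

setMethod("show", "SignatureCounts", function(object) {
    cat("SignatureCounts:", object@total, "substitutions over 96 classes\n")
    blk <- substr(names(object@counts), 3L, 5L)
    print(vapply(split(object@counts, blk), sum, 1L))
})

#' @rdname PhaseCall-class
#' @export
setMethod("phaseVerdict", "PhaseCall", function(x) x@verdict)

#' @rdname PhaseCall-class
#' @export
setMethod("phaseCounts", "PhaseCall", function(x) {
    c(A_only = x@n_A_only, B_only = x@n_B_only,
      both = x@n_both, neither = x@n_neither)
})

setMethod("show", "PhaseCall", function(object) {
    k <- phaseCounts(object)
    cat("PhaseCall:", object@verdict,
        sprintf("(A-only %d, B-only %d, both %d, neither %d; min %d)\n",
                k[1L], k[2L], k[3L], k[4L], object@min_fragments))
})
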
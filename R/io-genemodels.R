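#' Construct a GeneModelSet from per-gene exon ranges
#'
#' Exons supplied for each gene (possibly from several isoforms, possibly
#' overlapping) are merged into their union and sorted; introns are derived
#' as the gaps between consecutive exons of the union.
#'
#' @param exons A named [GenomicRanges::GRangesList], one element per gene
#'   symbol, or a named list of [GenomicRanges::GRanges].
#' @return A [GeneModelSet-class] object.
#' @examples
#' gm <- GeneModelSet(GenomicRanges::GRangesList(
#'     TP53ish = GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(c(101, 301, 601), c(200, 400, 700)), "+")))
#' nExons(gm)
#' @export
GeneModelSet <- function(exons) {
    if (is.list(exons)) exons <- GRangesList(exons)
    merged <- GenomicRanges::reduce(exons)
    new("GeneModelSet", exons = merged)
}

#' Read gene models from refFlat or BED12
#'
#' Exon coordinates per gene symbol are taken from a UCSC Table Browser style
#' annotation. All transcripts of a symbol are collapsed to their exon union:
#' the method detects retrocopies of genes, not of transcripts, and the union
#' is the most permissive exon assignment. Output is sorted by chromosome and
#' start.
#'
#' @param path Path to the annotation file.
#' @param dialect `"refflat"` (11-column refFlat as distributed by the UCSC
#'   Table Browser) or `"bed12"`.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path, dialect = c("refflat", "bed12")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("gene model file not found: ", path)
    if (dialect == "bed12") {
        gr <- rtracklayer::import(path, format = "bed")
        if (any(is.na(gr$name)) || any(gr$name == ""))
            stop("BED12 record without a name field")
        bl <- rtracklayer::blocks(gr)
        names(bl) <- gr$name
        ex <- unlist(bl, use.names = FALSE)
        per <- S4Vectors::split(ex,
            rep(gr$name, S4Vectors::elementNROWS(bl)))
    } else {
        tab <- read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
        if (ncol(tab) < 11L)
            stop("refFlat needs 11 columns, found ", ncol(tab))
        colnames(tab)[c(1, 3, 4, 9, 10, 11)] <-
            c("geneName", "chrom", "strand", "exonCount",
              "exonStarts", "exonEnds")
        starts <- lapply(strsplit(tab$exonStarts, ","),
                         function(x) as.integer(x[x != ""]))
        ends <- lapply(strsplit(tab$exonEnds, ","),
                       function(x) as.integer(x[x != ""]))
        n <- lengths(starts)
        if (any(n != lengths(ends)) || any(n != tab$exonCount))
            stop("exonStarts/exonEnds length mismatch in refFlat record(s): ",
                 paste(which(n != lengths(ends) | n != tab$exonCount),
                       collapse = ", "))
        if (any(n == 0L))
            stop("zero-exon refFlat record(s): ",
                 paste(which(n == 0L), collapse = ", "))
        ## refFlat exon coordinates are 0-based half-open
        ex <- GRanges(rep(tab$chrom, n),
                      IRanges(start = unlist(starts) + 1L,
                              end = unlist(ends)),
                      strand = rep(tab$strand, n))
        per <- S4Vectors::split(ex, rep(tab$geneName, n))
    }
    gms <- GeneModelSet(per)
    o <- order(geneChroms(gms),
               vapply(as.list(exons(gms)), function(g) min(start(g)), 1L))
    gms[o]
}

#' Write gene models to BED12
#'
#' One BED12 line per gene, blocks holding the exon union. Re-reading the
#' file with [readGeneModels()] restores the exon coordinates exactly.
#'
#' @param x A [GeneModelSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed12 <- function(x, path) {
    rtracklayer::export(exons(x), path, format = "bed")
    invisible(path)
}

#' Write gene models as refFlat
#'
#' Emits the 11-column refFlat dialect (0-based half-open exon coordinates),
#' one transcript per gene named after the gene symbol. Used by the simulator
#' so detection runs consume the same annotation format as a real analysis.
#'
#' @param x A [GeneModelSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRefFlat <- function(x, path) {
    ex <- exons(x)
    lines <- vapply(seq_along(ex), function(i) {
        g <- ex[[i]]
        paste(names(ex)[i], paste0(names(ex)[i], ".t1"),
              as.character(seqnames(g)[1L]), as.character(strand(g)[1L]),
              min(start(g)) - 1L, max(end(g)), min(start(g)) - 1L,
              max(end(g)), length(g),
              paste0(paste(start(g) - 1L, collapse = ","), ","),
              paste0(paste(end(g), collapse = ","), ","),
              sep = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}
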
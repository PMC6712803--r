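## Retrocopy detection from intron-spanning exome read pairs.
##
## Evidence model: a retrotransposed (intronless) copy of a spliced gene
## yields exome fragments whose reads map back to the source exons; a pair
## whose mates came from different exons acquires an ostensible template
## length inflated by every intervening intron. Filtering pairs on mapping
## quality and template length, crediting them to genes whose exons contain
## both mates, and requiring enough independently supported exons gives the
## candidate list.

#' Filter read pairs on mapping quality and ostensible template length
#'
#' Retains pairs whose mates BOTH have mapping quality at or above
#' `min_mapq` and whose ostensible template length is at or above `min_tlen`
#' (boundaries inclusive). The mapping-quality cut is applied to both mates
#' because a uniquely mapped read paired with a multi-mapper would fabricate
#' long templates. Drop reasons are counted in the parse log.
#'
#' @param pairs A [ReadPairSet-class].
#' @param params A [DetectionParams-class].
#' @return A filtered [ReadPairSet-class]; `parseLog()` gains counters
#'   `dropped_mapq` and `dropped_tlen`.
#' @export
filterPairs <- function(pairs, params = detectionParams()) {
    p <- pairData(pairs)
    ok_mapq <- p$m1_mapq >= params@min_mapq & p$m2_mapq >= params@min_mapq
    ok_tlen <- p$tlen >= params@min_tlen
    keep <- ok_mapq & ok_tlen
    lg <- parseLog(pairs)
    lg$dropped_mapq <- sum(!ok_mapq)
    lg$dropped_tlen <- sum(ok_mapq & !ok_tlen)
    lg$pairs_passing <- sum(keep)
    new("ReadPairSet", pairs = p[keep, , drop = FALSE], log = lg)
}

#' Accumulate per-gene exon support from read pairs
#'
#' A pair contributes to gene `g` if and only if both of its mates overlap
#' exons of `g`; each mate then increments the read-end count of every exon
#' of `g` it overlaps. Pairs whose mates lie in two different exons are
#' additionally recorded as bridging pairs. Pairs overlapping no gene, or
#' only intronic sequence, contribute nothing. When gene models overlap
#' (e.g. nested genes), a pair is credited to every gene whose exons contain
#' both mates, and the number of such multiply credited pairs is reported.
#'
#' Exon indices are 1-based positions within the gene's sorted exon union.
#'
#' @param pairs A (typically filtered) [ReadPairSet-class].
#' @param genes A [GeneModelSet-class].
#' @return Named list, one element per gene with at least one contributing
#'   pair: `list(counts = <read ends per exon>, n_pairs, bridging =
#'   data.frame(fragment_id, exon1, exon2))`. Attribute `n_ambiguous` counts
#'   pairs credited to more than one gene.
#' @export
assignToGenes <- function(pairs, genes) {
    p <- pairData(pairs)
    ex <- exons(genes)
    nex <- S4Vectors::elementNROWS(ex)
    flat <- unlist(ex, use.names = FALSE)
    gene_of <- rep(seq_along(ex), nex)
    exon_of <- unlist(lapply(nex, seq_len), use.names = FALSE)
    if (nrow(p) == 0L) {
        out <- list()
        attr(out, "n_ambiguous") <- 0L
        return(out)
    }
    m1 <- GRanges(p$chrom, IRanges(p$m1_start, p$m1_end))
    m2 <- GRanges(p$chrom, IRanges(p$m2_start, p$m2_end))
    hit <- function(gr) {
        ov <- findOverlaps(gr, flat)
        data.frame(pair = queryHits(ov), gene = gene_of[subjectHits(ov)],
                   exon = exon_of[subjectHits(ov)])
    }
    h1 <- hit(m1)
    h2 <- hit(m2)
    ## (pair, gene) combinations with both mates exonic
    k1 <- unique(h1[c("pair", "gene")])
    k2 <- unique(h2[c("pair", "gene")])
    both <- merge(k1, k2)
    out <- list()
    attr(out, "n_ambiguous") <-
        sum(table(both$pair) > 1L)
    if (nrow(both) == 0L) return(out)
    key <- function(d) paste(d$pair, d$gene)
    h1 <- h1[key(h1) %in% key(both), , drop = FALSE]
    h2 <- h2[key(h2) %in% key(both), , drop = FALSE]
    for (g in sort(unique(both$gene))) {
        g1 <- h1[h1$gene == g, , drop = FALSE]
        g2 <- h2[h2$gene == g, , drop = FALSE]
        counts <- tabulate(c(g1$exon, g2$exon), nbins = nex[g])
        ## bridging: first overlapped exon of each mate differs
        e1 <- vapply(split(g1$exon, g1$pair), min, 1L)
        e2 <- vapply(split(g2$exon, g2$pair), min, 1L)
        pid <- sort(unique(both$pair[both$gene == g]))
        e1 <- e1[as.character(pid)]
        e2 <- e2[as.character(pid)]
        br <- which(e1 != e2)
        out[[names(ex)[g]]] <- list(
            counts = counts,
            n_pairs = length(pid),
            bridging = data.frame(
                fragment_id = p$fragment_id[pid[br]],
                exon1 = unname(e1[br]), exon2 = unname(e2[br])))
    }
    out
}

#' Call retrocopy candidates from exon support
#'
#' A gene is emitted as a candidate when (i) it bears introns (at least two
#' exons) and (ii) the set of its exons supported by at least
#' `min_reads_per_exon` read ends has size at least `min_supported_exons`
#' ("spanning more than 2 discrete exons" at the defaults). Output is sorted
#' by decreasing number of supporting pairs, ties broken by gene symbol.
#'
#' @param support Output of [assignToGenes()].
#' @param genes The [GeneModelSet-class] the support was built against.
#' @param params A [DetectionParams-class].
#' @param sample_id Sample label for the output rows.
#' @return A [S4Vectors::DataFrame] with columns `sample_id`, `gene`,
#'   `chrom`, `n_supported_exons`, `supported_exons` (integer list),
#'   `reads_per_exon` (integer list, counts of the supported exons),
#'   `n_pairs` and `flags` (comma string, empty initially).
#' @export
callCandidates <- function(support, genes, params = detectionParams(),
                           sample_id = "sample") {
    nex <- nExons(genes)
    chroms <- geneChroms(genes)
    rows <- lapply(names(support), function(sym) {
        s <- support[[sym]]
        if (nex[[sym]] < 2L) return(NULL)
        supp <- which(s$counts >= params@min_reads_per_exon)
        if (length(supp) < params@min_supported_exons) return(NULL)
        list(gene = sym, chrom = chroms[[sym]],
             n_supported_exons = length(supp), supported = supp,
             reads = s$counts[supp], n_pairs = s$n_pairs)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0L) return(.emptyCandidates())
    out <- DataFrame(
        sample_id = rep(sample_id, length(rows)),
        gene = vapply(rows, `[[`, "", "gene"),
        chrom = vapply(rows, `[[`, "", "chrom"),
        n_supported_exons = vapply(rows, `[[`, 1L, "n_supported_exons"),
        supported_exons = IRanges::IntegerList(lapply(rows, `[[`,
                                                      "supported")),
        reads_per_exon = IRanges::IntegerList(lapply(rows, `[[`, "reads")),
        n_pairs = vapply(rows, `[[`, 1L, "n_pairs"),
        flags = rep("", length(rows)))
    out[order(-out$n_pairs, out$gene), , drop = FALSE]
}

.emptyCandidates <- function() {
    DataFrame(sample_id = character(0), gene = character(0),
              chrom = character(0), n_supported_exons = integer(0),
              supported_exons = IRanges::IntegerList(),
              reads_per_exon = IRanges::IntegerList(),
              n_pairs = integer(0), flags = character(0))
}

#' Flag candidates matching known retrocopies
#'
#' Candidates whose source gene appears in a list of known retrocopied genes
#' (e.g. the UCSC retroposed-genes track or retrogeneDB, supplied as gene
#' symbols or as a BED of retrocopy parent loci) gain the flag
#' `known_retrocopy`. No candidate is removed: the flag marks prior evidence,
#' not an artifact.
#'
#' @param candidates Candidate [S4Vectors::DataFrame] from
#'   [callCandidates()].
#' @param known Character vector of gene symbols, a `GRanges` of parent
#'   loci, or a path to a BED file of such loci (the `name` column carries
#'   the symbol).
#' @param genes Optional [GeneModelSet-class], needed to intersect candidate
#'   loci with interval-form `known`.
#' @return `candidates` with updated `flags`.
#' @export
annotateKnown <- function(candidates, known, genes = NULL) {
    if (is.character(known) && length(known) == 1L && file.exists(known))
        known <- rtracklayer::import(known, format = "bed")
    if (length(known) == 0L) {
        warning("empty known-retrocopy list; no candidates flagged")
        return(candidates)
    }
    if (nrow(candidates) == 0L) return(candidates)
    if (methods::is(known, "GRanges")) {
        syms <- as.character(known$name)
        if (!is.null(genes)) {
            span <- unlist(range(exons(genes)), use.names = FALSE)
            names(span) <- geneSymbols(genes)
            ov <- findOverlaps(span, known)
            syms <- union(syms, names(span)[queryHits(ov)])
        }
        known <- syms
    }
    hitidx <- candidates$gene %in% known
    candidates$flags[hitidx] <- ifelse(
        candidates$flags[hitidx] == "", "known_retrocopy",
        paste(candidates$flags[hitidx], "known_retrocopy", sep = ","))
    candidates
}

#' Detect retrocopy candidates in one sample
#'
#' Composition of the full per-sample pipeline: read pairs from SAM, filter
#' on mapping quality and ostensible template length, credit pairs to genes
#' whose exons contain both mates, and call genes with enough independently
#' supported exons. Per-stage counts are attached as
#' `metadata(result)$stage_counts`, and a TSV report is written when `out`
#' is given.
#'
#' @param sam_path SAM file of one sample.
#' @param gene_models A [GeneModelSet-class], or a path to an annotation
#'   file read with `dialect`.
#' @param params A [DetectionParams-class].
#' @param dialect Annotation dialect when `gene_models` is a path.
#' @param known Optional known-retrocopy list for [annotateKnown()].
#' @param sample_id Sample label; defaults to the SAM file name.
#' @param out Optional path for a TSV report ([writeCandidatesTsv()]).
#' @return Candidate [S4Vectors::DataFrame] (see [callCandidates()]).
#' @export
detectSample <- function(sam_path, gene_models,
                         params = detectionParams(),
                         dialect = c("refflat", "bed12"), known = NULL,
                         sample_id = NULL, out = NULL) {
    if (is.character(gene_models))
        gene_models <- readGeneModels(gene_models, match.arg(dialect))
    pairs <- readSamPairs(sam_path, sample_id = sample_id)
    sample_id <- pairData(pairs)$sample_id[1L]
    if (is.na(sample_id) || is.null(sample_id))
        sample_id <- sub("\\.(sam|bam)$", "", basename(sam_path))
    kept <- filterPairs(pairs, params)
    support <- assignToGenes(kept, gene_models)
    cand <- callCandidates(support, gene_models, params,
                           sample_id = sample_id)
    if (!is.null(known)) cand <- annotateKnown(cand, known, gene_models)
    lg <- parseLog(kept)
    lg$n_ambiguous_pairs <- attr(support, "n_ambiguous")
    lg$n_candidates <- nrow(cand)
    metadata(cand)$stage_counts <- lg
    if (!is.null(out)) writeCandidatesTsv(cand, out)
    cand
}

#' Write a candidate table as TSV
#'
#' Columns: `sample`, `gene`, `chrom`, `n_supported_exons`,
#' `supported_exon_indices` (comma-separated, 1-based), `n_pairs`, `flags`.
#'
#' @param candidates Candidate [S4Vectors::DataFrame].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCandidatesTsv <- function(candidates, path) {
    df <- data.frame(
        sample = candidates$sample_id, gene = candidates$gene,
        chrom = candidates$chrom,
        n_supported_exons = candidates$n_supported_exons,
        supported_exon_indices = vapply(candidates$supported_exons,
                                        paste, "", collapse = ","),
        n_pairs = candidates$n_pairs, flags = candidates$flags)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a candidate TSV back into a candidate table
#'
#' @param path TSV written by [writeCandidatesTsv()].
#' @return Candidate [S4Vectors::DataFrame].
#' @export
readCandidatesTsv <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE,
                     colClasses = c(sample = "character",
                                    gene = "character",
                                    chrom = "character",
                                    flags = "character"))
    supp <- lapply(strsplit(as.character(df$supported_exon_indices), ","),
                   as.integer)
    DataFrame(sample_id = df$sample, gene = df$gene, chrom = df$chrom,
              n_supported_exons = df$n_supported_exons,
              supported_exons = IRanges::IntegerList(supp),
              reads_per_exon = IRanges::IntegerList(
                  rep(list(integer(0)), nrow(df))),
              n_pairs = df$n_pairs,
              flags = ifelse(is.na(df$flags), "", df$flags))
}
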
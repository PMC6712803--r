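## Shared fixtures: tiny gene models, hand-built SAM pairs, and independent
## brute-force oracles for the detection math.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(SummarizedExperiment)
})

## G1: 3 exons with 300-bp introns; G2: single exon; G3: 2 exons (chr2).
tinyGenes <- function() {
    GeneModelSet(GRangesList(
        G1 = GRanges("chr1", IRanges(c(1001, 1501, 2001),
                                     c(1200, 1700, 2200)), "+"),
        G2 = GRanges("chr1", IRanges(5001, 5400), "+"),
        G3 = GRanges("chr2", IRanges(c(101, 1601), c(300, 1800)), "-")))
}

## Write a SAM of proper pairs; input columns: qname, chrom, pos1, pos2
## (1-based), optional cigar1/cigar2 (default 100M), mapq1/mapq2.
pairSam <- function(df, path, seqlengths = c(chr1 = 10000, chr2 = 10000)) {
    n <- nrow(df)
    cig <- function(x, d) if (is.null(x)) rep(d, n) else x
    rec <- data.frame(
        qname = rep(df$qname, each = 2L),
        flag = rep(c(99L, 147L), n),
        rname = as.vector(rbind(df$chrom,
                                if (is.null(df$chrom2)) df$chrom
                                else df$chrom2)),
        pos = as.vector(rbind(df$pos1, df$pos2)),
        mapq = as.vector(rbind(
            if (is.null(df$mapq1)) rep(60L, n) else df$mapq1,
            if (is.null(df$mapq2)) rep(60L, n) else df$mapq2)),
        cigar = as.vector(rbind(cig(df$cigar1, "100M"),
                                cig(df$cigar2, "100M"))),
        rnext = "=",
        pnext = as.vector(rbind(df$pos2, df$pos1)),
        tlen = 0L, seq = "*", qual = "*")
    if (!is.null(df$chrom2))
        rec$rnext <- as.vector(rbind(df$chrom2, df$chrom))
    writeSamFile(rec, seqlengths, path)
    path
}

## Build a ReadPairSet directly (bypassing SAM) for filter tests.
makePairSet <- function(chrom, p1s, p1e, q1, p2s, p2e, q2,
                        sample_id = "s") {
    n <- length(p1s)
    p <- DataFrame(sample_id = rep(sample_id, n),
                   fragment_id = paste0("f", seq_len(n)),
                   chrom = rep(chrom, length.out = n),
                   m1_start = as.integer(p1s), m1_end = as.integer(p1e),
                   m1_mapq = as.integer(q1),
                   m2_start = as.integer(p2s), m2_end = as.integer(p2e),
                   m2_mapq = as.integer(q2),
                   proper_orientation = rep(TRUE, n))
    p$tlen <- pmax(p$m1_end, p$m2_end) - pmin(p$m1_start, p$m2_start) + 1L
    new("ReadPairSet", pairs = p, log = list())
}

## Base-by-base cDNA -> genome map: position vector indexed by cDNA base.
## Independent of mapCdnaToGenome (pure seq() construction).
cdnaMapOracle <- function(gene) {
    unlist(Map(seq, start(gene), end(gene)), use.names = FALSE)
}

## Brute-force candidate caller: tests every gene against the definition
## directly with scalar loops. Returns sorted candidate symbols.
bruteCandidates <- function(pairs, genes, params = detectionParams()) {
    p <- as.data.frame(pairData(pairs))
    ex <- exons(genes)
    called <- character(0)
    for (sym in geneSymbols(genes)) {
        g <- ex[[sym]]
        if (length(g) < 2L) next
        if (nrow(p) == 0L) next
        counts <- rep(0L, length(g))
        npairs <- 0L
        for (i in seq_len(nrow(p))) {
            if (p$chrom[i] != as.character(seqnames(g)[1L])) next
            ovl <- function(s, e)
                which(s <= end(g) & e >= start(g))
            e1 <- ovl(p$m1_start[i], p$m1_end[i])
            e2 <- ovl(p$m2_start[i], p$m2_end[i])
            if (length(e1) == 0L || length(e2) == 0L) next
            npairs <- npairs + 1L
            for (k in e1) counts[k] <- counts[k] + 1L
            for (k in e2) counts[k] <- counts[k] + 1L
        }
        supported <- sum(counts >= params@min_reads_per_exon)
        if (npairs >= 1L && supported >= params@min_supported_exons)
            called <- c(called, sym)
    }
    sort(called)
}

## Candidate table stub for cohort tests.
fakeCand <- function(sample_id, genes, chroms = "chr1") {
    n <- length(genes)
    DataFrame(sample_id = rep(sample_id, n), gene = genes,
              chrom = rep(chroms, length.out = n),
              n_supported_exons = rep(3L, n),
              supported_exons = IRanges::IntegerList(
                  rep(list(1:3), n)),
              reads_per_exon = IRanges::IntegerList(
                  rep(list(c(2L, 2L, 2L)), n)),
              n_pairs = rep(5L, n), flags = rep("", n))
}

sampleSheet <- function(ids, donors, types) {
    data.frame(sample_id = ids, donor_id = donors, cell_type = types)
}
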
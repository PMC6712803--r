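#' Read primary read pairs from a SAM file
#'
#' Pairs primary alignments by query name and emits one record per pair with
#' both mates mapped to the same chromosome. The ostensible template length is
#' recomputed as the reference-coordinate span of the two mates
#' (`max(end) - min(start) + 1`), never taken from the TLEN column, so that
#' the quantity the retrocopy filter thresholds is aligner-independent.
#' Secondary and supplementary alignments, unmapped mates, cross-chromosome
#' pairs and mates left unmatched at end of file are dropped (with a warning
#' and counters in the parse log).
#'
#' @param path Path to a SAM file with a header (BAM is accepted too).
#' @param sample_id Sample label stored with every pair; defaults to the file
#'   name without extension.
#' @return A [ReadPairSet-class]; `parseLog()` holds the record counts.
#' @export
readSamPairs <- function(path, sample_id = NULL) {
    if (!file.exists(path)) stop("SAM file not found: ", path)
    if (is.null(sample_id))
        sample_id <- sub("\\.(sam|bam)$", "", basename(path))
    is_sam <- !grepl("\\.bam$", path, ignore.case = TRUE)
    if (is_sam) {
        .validateSamText(path)
        bam <- suppressMessages(
            Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE))
        on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    } else {
        bam <- path
    }
    fl <- scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                      hasUnmappedMate = FALSE, isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE)
    n_records <- Rsamtools::countBam(bam,
        param = ScanBamParam(flag = fl))$records
    gp <- readGAlignmentPairs(bam, use.names = TRUE,
        param = ScanBamParam(what = "mapq", flag = fl))
    m1 <- GenomicAlignments::first(gp)
    m2 <- GenomicAlignments::second(gp)
    ## mates on different chromosomes carry no template length
    same_chrom <- as.character(seqnames(m1)) == as.character(seqnames(m2))
    gp <- gp[same_chrom]
    m1 <- m1[same_chrom]
    m2 <- m2[same_chrom]
    n_dropped <- n_records - 2L * length(gp)
    if (n_dropped > 0L)
        warning(n_dropped, " record(s) dropped: unmatched mate or ",
                "cross-chromosome pair")
    p <- DataFrame(
        sample_id = rep(sample_id, length(gp)),
        fragment_id = names(gp),
        chrom = as.character(seqnames(m1)),
        m1_start = start(m1), m1_end = end(m1),
        m1_mapq = S4Vectors::mcols(m1)$mapq,
        m2_start = start(m2), m2_end = end(m2),
        m2_mapq = S4Vectors::mcols(m2)$mapq,
        proper_orientation = as.character(strand(m1)) !=
            as.character(strand(m2)))
    p$tlen <- pmax(p$m1_end, p$m2_end) - pmin(p$m1_start, p$m2_start) + 1L
    p <- p[, c("sample_id", "fragment_id", "chrom", "m1_start", "m1_end",
               "m1_mapq", "m2_start", "m2_end", "m2_mapq", "tlen",
               "proper_orientation")]
    new("ReadPairSet", pairs = p,
        log = list(records_read = n_records, pairs_emitted = length(gp),
                   records_dropped = n_dropped))
}

## Cheap structural scan so a truncated/corrupt SAM fails with the offending
## line number instead of an opaque converter error.
.validateSamText <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "@")
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf < 11L))
        stop("malformed SAM line ", which(body)[which(nf < 11L)[1L]],
             " in ", path, " (fewer than 11 fields)")
    invisible(TRUE)
}

## Read alignments with sequence and CIGAR (for per-read allele extraction).
.readSamAlignments <- function(path) {
    .validateSamText(path)
    bam <- suppressMessages(
        Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                         indexDestination = TRUE))
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    fl <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE)
    readGAlignments(bam, use.names = TRUE,
        param = ScanBamParam(what = c("seq", "mapq"), flag = fl))
}

#' Write alignment records as SAM text
#'
#' Low-level writer used by the simulator. `records` is a data.frame with the
#' eleven mandatory SAM columns (`qname`, `flag`, `rname`, `pos`, `mapq`,
#' `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`); `seqlengths` a named
#' integer vector naming the reference sequences for the header.
#'
#' @param records data.frame of SAM fields, one row per alignment line.
#' @param seqlengths Named integer vector (reference name -> length).
#' @param path Output path.
#' @param sample_id Optional read-group sample for the header.
#' @return `path`, invisibly.
#' @export
writeSamFile <- function(records, seqlengths, path, sample_id = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                       as.integer(seqlengths)), con)
    if (!is.null(sample_id))
        writeLines(sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id), con)
    if (nrow(records) > 0L) {
        int_cols <- c("flag", "pos", "mapq", "pnext", "tlen")
        records[int_cols] <- lapply(records[int_cols], as.integer)
        lines <- do.call(paste,
            c(lapply(records[c("qname", "flag", "rname", "pos", "mapq",
                               "cigar", "rnext", "pnext", "tlen", "seq",
                               "qual")], as.character),
              sep = "\t"))
        writeLines(lines, con)
    }
    invisible(path)
}
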
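#' Read biallelic SNVs from a VCF
#'
#' Returns the single-nucleotide substitutions of the first sample in the
#' file as a [GenomicRanges::GRanges] with metadata columns `ref`, `alt`,
#' `depth` (the DP genotype field; `NA` when absent, which fails the depth
#' filter downstream), `genotype` (`"het"` or `"hom"`) and `filter` (the VCF
#' FILTER column). Indels and multi-allelic records are skipped and counted
#' in `metadata(x)$n_skipped`.
#'
#' @param path Path to a VCF 4.x file.
#' @return A `GRanges` of SNVs.
#' @export
readVcfSnvs <- function(path) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "ref"))
    keep <- isSNV(vcf, singleAltOnly = TRUE)
    n_skipped <- sum(!keep)
    vcf <- vcf[keep, ]
    rr <- SummarizedExperiment::rowRanges(vcf)
    gt <- geno(vcf)$GT[, 1L]
    depth <- if ("DP" %in% names(geno(vcf))) {
        as.integer(geno(vcf)$DP[, 1L])
    } else {
        rep(NA_integer_, length(vcf))
    }
    out <- granges(rr)
    S4Vectors::mcols(out) <- DataFrame(
        ref = as.character(ref(vcf)),
        alt = as.character(unlist(alt(vcf))),
        depth = depth,
        genotype = ifelse(gt %in% c("1/1", "1|1"), "hom", "het"),
        filter = as.character(rr$FILTER))
    names(out) <- NULL
    metadata(out)$n_skipped <- n_skipped
    out
}

#' Write a minimal single-sample VCF
#'
#' Emits a VCF 4.2 file with GT and DP genotype fields, as produced by the
#' simulator. `variants` is a `GRanges` with metadata columns `ref`, `alt`,
#' `depth`, `genotype` (and optionally `filter`, default `PASS`).
#'
#' @param variants `GRanges` of single-base records.
#' @param sample_id Sample column name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVcfFile <- function(variants, sample_id, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               sample_id)), con)
    if (length(variants) > 0L) {
        o <- order(as.character(seqnames(variants)), start(variants))
        v <- variants[o]
        gt <- ifelse(S4Vectors::mcols(v)$genotype == "hom", "1/1", "0/1")
        filt <- S4Vectors::mcols(v)$filter
        if (is.null(filt)) filt <- rep("PASS", length(v))
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:DP\t%s:%d",
                           as.character(seqnames(v)), start(v),
                           S4Vectors::mcols(v)$ref, S4Vectors::mcols(v)$alt,
                           filt, gt,
                           as.integer(S4Vectors::mcols(v)$depth)), con)
    }
    invisible(path)
}
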
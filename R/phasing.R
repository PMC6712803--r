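## Read-backed cis/trans phasing of two nearby variants. Two heterozygous
## variants close enough to be spanned by one sequencing fragment can be
## phased directly: fragments carrying one alternate allele but never both
## place the variants on opposite homologs (trans, i.e. compound
## heterozygous); fragments carrying both or neither place them in cis.

#' Describe an SNV for phasing
#'
#' @param chrom Chromosome.
#' @param pos 1-based position.
#' @param ref,alt Single reference/alternate bases.
#' @return A list with class `"snv"`.
#' @export
snvVariant <- function(chrom, pos, ref, alt) {
    stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt)
    structure(list(chrom = chrom, start = as.integer(pos),
                   end = as.integer(pos), ref = ref, alt = alt),
              class = "snv")
}

#' Describe a deletion for phasing
#'
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive bounds of the deleted reference bases
#'   (genome-browser convention).
#' @return A list with class `"deletion"`.
#' @export
deletionVariant <- function(chrom, start, end) {
    if (end < start) stop("deletion end before start")
    structure(list(chrom = chrom, start = as.integer(start),
                   end = as.integer(end)), class = "deletion")
}

#' Span of a variant in bp
#'
#' For 1-based inclusive coordinates the span is `end - start + 1`; a
#' single-base variant has span 1.
#'
#' @param v A variant from [snvVariant()] or [deletionVariant()], or
#'   anything with `start` and `end` elements.
#' @return Integer length in bp.
#' @examples
#' variantSpan(deletionVariant("chr19", 45352505, 45352527))  # 23
#' @export
variantSpan <- function(v) {
    if (v$end < v$start) stop("end before start")
    v$end - v$start + 1L
}

#' Phase verdict from fragment class counts
#'
#' Verdict `trans` requires at least `min_fragments` fragments carrying only
#' the first alternate allele, at least `min_fragments` carrying only the
#' second, and ZERO carrying both; `cis` requires at least `min_fragments`
#' carrying both and zero carrying exactly one. Anything else is
#' `ambiguous`. The strict zero on the opposing class reflects that the
#' compound-heterozygosity conclusion rests on the absence of dual-variant
#' fragments.
#'
#' @param n_A_only,n_B_only,n_both,n_neither Fragment counts.
#' @param min_fragments Evidence threshold (default 3).
#' @return A [PhaseCall-class].
#' @export
phaseFromCounts <- function(n_A_only, n_B_only, n_both, n_neither,
                            min_fragments = 3L) {
    verdict <- if (n_A_only >= min_fragments && n_B_only >= min_fragments &&
                   n_both == 0L) {
        "trans"
    } else if (n_both >= min_fragments && n_A_only == 0L &&
               n_B_only == 0L) {
        "cis"
    } else "ambiguous"
    new("PhaseCall", n_A_only = as.integer(n_A_only),
        n_B_only = as.integer(n_B_only), n_both = as.integer(n_both),
        n_neither = as.integer(n_neither), verdict = verdict,
        min_fragments = as.integer(min_fragments))
}

## Observed allele of one read at an SNV locus: "alt", "ref" or NA.
.snvAlleleInRead <- function(pos, aln_start, cig, seq, ref, alt) {
    ops <- explodeCigarOps(cig)[[1L]]
    lens <- explodeCigarOpLengths(cig)[[1L]]
    r <- aln_start
    q <- 1L
    for (i in seq_along(ops)) {
        op <- ops[i]; len <- lens[i]
        if (op %in% c("M", "=", "X")) {
            if (pos >= r && pos < r + len) {
                b <- substr(seq, q + (pos - r), q + (pos - r))
                return(if (b == alt) "alt" else if (b == ref) "ref"
                       else NA_character_)
            }
            r <- r + len; q <- q + len
        } else if (op %in% c("I", "S")) {
            q <- q + len
        } else if (op %in% c("D", "N")) {
            if (pos >= r && pos < r + len) return(NA_character_)
            r <- r + len
        } else if (op == "H") {
            ## consumes nothing relevant
        }
    }
    NA_character_
}

## Observed allele of one read at a deletion locus. A read supports the
## deletion when a D operation covers the interval, the reference when it
## aligns across the whole interval without a deletion.
.delAlleleInRead <- function(del_start, del_end, aln_start, cig) {
    ops <- explodeCigarOps(cig)[[1L]]
    lens <- explodeCigarOpLengths(cig)[[1L]]
    r <- aln_start
    for (i in seq_along(ops)) {
        op <- ops[i]; len <- lens[i]
        if (op %in% c("M", "=", "X", "D", "N")) {
            if (op %in% c("D", "N") &&
                r <= del_start && del_end < r + len)
                return("alt")
            r <- r + len
        }
    }
    aln_end <- r - 1L
    if (aln_start <= del_start && del_end <= aln_end) return("ref")
    NA_character_
}

#' Phase two nearby variants from read alignments
#'
#' Classifies every fragment (read pair) by the alleles it shows at the two
#' loci -- alternate at the first only, at the second only, at both, or
#' reference at both -- and applies the decision rule of
#' [phaseFromCounts()]. A fragment is informative only when it reports a
#' consistent allele at both loci; reads of one fragment disagreeing at a
#' locus make it uninformative. The verdict is invariant to fragment order
#' and symmetric under swapping the two variants.
#'
#' @param sam_path SAM file of alignments over the region.
#' @param varA,varB Variants from [snvVariant()] / [deletionVariant()], on
#'   one chromosome.
#' @param min_fragments Evidence threshold (default 3).
#' @return A [PhaseCall-class]; zero informative fragments warn and yield
#'   `ambiguous`.
#' @export
phaseTwoVariants <- function(sam_path, varA, varB, min_fragments = 3L) {
    if (varA$chrom != varB$chrom)
        stop("variants must lie on one chromosome")
    aln <- .readSamAlignments(sam_path)
    obs <- function(v) {
        vapply(seq_along(aln), function(i) {
            if (as.character(seqnames(aln))[i] != v$chrom)
                return(NA_character_)
            if (inherits(v, "snv")) {
                .snvAlleleInRead(v$start, start(aln)[i], cigar(aln)[i],
                                 as.character(
                                     S4Vectors::mcols(aln)$seq[[i]]),
                                 v$ref, v$alt)
            } else {
                .delAlleleInRead(v$start, v$end, start(aln)[i],
                                 cigar(aln)[i])
            }
        }, "")
    }
    oa <- obs(varA)
    ob <- obs(varB)
    frag <- names(aln)
    consensus <- function(x) {
        u <- unique(x[!is.na(x)])
        if (length(u) == 1L) u else NA_character_
    }
    fa <- vapply(split(oa, frag), consensus, "")
    fb <- vapply(split(ob, frag), consensus, "")
    informative <- !is.na(fa) & !is.na(fb)
    if (!any(informative))
        warning("no fragment covers both loci informatively")
    a <- fa[informative]; b <- fb[informative]
    phaseFromCounts(
        n_A_only = sum(a == "alt" & b == "ref"),
        n_B_only = sum(a == "ref" & b == "alt"),
        n_both = sum(a == "alt" & b == "alt"),
        n_neither = sum(a == "ref" & b == "ref"),
        min_fragments = min_fragments)
}
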
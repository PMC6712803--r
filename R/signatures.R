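## 96-class single-base-substitution signatures from iPSC-vs-parent calls.
## Classes are the substitution expressed on the pyrimidine strand (C>A, C>G,
## C>T, T>A, T>C, T>G) crossed with the two flanking reference bases.

#' Canonical 96 SBS class labels
#'
#' Labels of the form `X[R>A]Y` in canonical order: substitution blocks C>A,
#' C>G, C>T, T>A, T>C, T>G, contexts lexicographic by 5' then 3' flank.
#'
#' @return Character vector of length 96.
#' @examples
#' head(sbsClasses())
#' @export
sbsClasses <- function() {
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    bases <- c("A", "C", "G", "T")
    unlist(lapply(subs, function(s)
        as.vector(t(outer(bases, bases, function(x, y)
            paste0(x, "[", s, "]", y))))))
}

.revcompChar <- function(x) {
    vapply(x, function(s) {
        if (is.na(s)) return(NA_character_)
        paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
              collapse = "")
    }, "", USE.NAMES = FALSE)
}

#' Classify substitutions into the 96 trinucleotide classes
#'
#' Expresses each substitution on the pyrimidine strand: when the reference
#' base is a purine (A or G), reference, alternate and trinucleotide context
#' are reverse-complemented before labeling, so e.g. G>A in context TGT and
#' C>T in context ACA are the same class `A[C>T]A`. Contexts containing `N`
#' classify to `NA`.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param context3 Reference trinucleotides centered on the variant; the
#'   middle base must equal `ref`.
#' @return Character vector of class labels (`NA` where unclassifiable).
#' @examples
#' classify96(c("C", "G", "T"), c("T", "A", "G"), c("ACA", "TGT", "TTG"))
#' @export
classify96 <- function(ref, alt, context3) {
    stopifnot(length(ref) == length(alt), length(ref) == length(context3))
    if (length(ref) == 0L) return(character(0))
    if (any(ref == alt, na.rm = TRUE)) stop("ref equals alt")
    bad_mid <- !is.na(context3) & substr(context3, 2L, 2L) != ref
    if (any(bad_mid))
        stop("context3 middle base disagrees with ref at position(s): ",
             paste(which(bad_mid), collapse = ", "))
    flip <- !is.na(ref) & ref %in% c("A", "G")
    ref[flip] <- chartr("AG", "TC", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context3[flip] <- .revcompChar(context3[flip])
    lab <- paste0(substr(context3, 1L, 1L), "[", ref, ">", alt, "]",
                  substr(context3, 3L, 3L))
    lab[is.na(context3) | grepl("N", context3, fixed = TRUE) |
        !ref %in% c("C", "T") | is.na(alt)] <- NA_character_
    lab
}

#' Somatic difference between an iPSC and its parental call set
#'
#' Because an iPSC line derives from a single parental cell, variants present
#' in the iPSC calls but absent (same chromosome, position and alternate
#' allele) from the parental calls are the line's somatic mutations.
#' Homozygous iPSC calls are retained: a somatic mutation followed by gene
#' conversion presents as homozygous.
#'
#' @param ipsc,parent `GRanges` of SNVs from [readVcfSnvs()], called against
#'   the same reference.
#' @return The somatic subset of `ipsc`.
#' @export
somaticDiff <- function(ipsc, parent) {
    key <- function(v) paste(as.character(seqnames(v)), start(v),
                             S4Vectors::mcols(v)$alt)
    pos <- function(v) paste(as.character(seqnames(v)), start(v))
    shared <- intersect(pos(ipsc), pos(parent))
    if (length(shared) > 0L) {
        ri <- setNames(S4Vectors::mcols(ipsc)$ref, pos(ipsc))[shared]
        rp <- setNames(S4Vectors::mcols(parent)$ref, pos(parent))[shared]
        if (any(ri != rp))
            stop("reference allele mismatch between call sets at ",
                 shared[which(ri != rp)[1L]],
                 "; were the files called against the same reference?")
    }
    ipsc[!key(ipsc) %in% key(parent)]
}

#' Filtering parameters for signature construction
#'
#' @slot min_depth Minimum read depth at the site in the iPSC sample
#'   (default 8, inclusive). Depth here is total site coverage (DP), not the
#'   alternate-allele count.
#' @slot excluded_regions `GRanges` of structural-mutation regions (deletion,
#'   copy-number gain, copy-neutral LOH, e.g. from SNP-array genotyping);
#'   variants inside them are removed since their genotypes are unreliable.
#' @slot require_pass Drop variants whose FILTER is not `PASS`/`.`
#'   (default `TRUE`).
#' @export
setClass("SignatureFilterParams", representation(
    min_depth = "integer", excluded_regions = "GRanges",
    require_pass = "logical"))

setValidity("SignatureFilterParams", function(object) {
    if (object@min_depth < 0L) return("min_depth must be >= 0")
    TRUE
})

#' @describeIn SignatureFilterParams-class Constructor.
#' @param min_depth,excluded_regions,require_pass See slots; `excluded_regions`
#'   may also be a BED file path.
#' @return A `SignatureFilterParams` object.
#' @export
signatureFilterParams <- function(min_depth = 8L,
                                  excluded_regions = GRanges(),
                                  require_pass = TRUE) {
    if (is.character(excluded_regions))
        excluded_regions <- rtracklayer::import(excluded_regions,
                                                format = "bed")
    new("SignatureFilterParams", min_depth = as.integer(min_depth),
        excluded_regions = granges(excluded_regions),
        require_pass = require_pass)
}

#' Apply depth, FILTER and structural-region filters
#'
#' Retains variants with depth at or above `min_depth` (unknown depth
#' fails), FILTER `PASS`/`.` when `require_pass`, and position outside every
#' excluded region. Drop reasons are counted in
#' `metadata(result)$filter_counts`.
#'
#' @param variants `GRanges` of SNVs (see [readVcfSnvs()]).
#' @param params A [SignatureFilterParams-class].
#' @return The filtered `GRanges`.
#' @export
applyVariantFilters <- function(variants, params = signatureFilterParams()) {
    mc <- S4Vectors::mcols(variants)
    ok_pass <- if (params@require_pass && !is.null(mc$filter)) {
        mc$filter %in% c("PASS", ".")
    } else rep(TRUE, length(variants))
    ok_depth <- !is.na(mc$depth) & mc$depth >= params@min_depth
    in_excl <- if (length(params@excluded_regions) > 0L) {
        IRanges::overlapsAny(variants, params@excluded_regions)
    } else rep(FALSE, length(variants))
    keep <- ok_pass & ok_depth & !in_excl
    out <- variants[keep]
    metadata(out)$filter_counts <- list(
        input = length(variants),
        dropped_filter = sum(!ok_pass),
        dropped_depth = sum(ok_pass & !ok_depth),
        dropped_excluded = sum(ok_pass & ok_depth & in_excl),
        retained = sum(keep))
    out
}

#' Attach trinucleotide contexts from a reference
#'
#' Fills the `context3` metadata column (reference trinucleotide centered on
#' each variant) by lookup in a reference sequence set. Variants at a contig
#' edge get `NA`.
#'
#' @param variants `GRanges` of SNVs.
#' @param reference A [Biostrings::DNAStringSet] named by chromosome, or a
#'   FASTA path.
#' @return `variants` with a `context3` column.
#' @export
addTrinucleotideContext <- function(variants, reference) {
    if (is.character(reference))
        reference <- readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
    ctx <- rep(NA_character_, length(variants))
    for (chr in unique(as.character(seqnames(variants)))) {
        if (!chr %in% names(reference))
            stop("chromosome ", chr, " absent from reference")
        i <- which(as.character(seqnames(variants)) == chr)
        p <- start(variants)[i]
        okb <- p > 1L & p < length(reference[[chr]])
        ctx[i[okb]] <- as.character(Biostrings::extractAt(
            reference[[chr]], IRanges(p[okb] - 1L, p[okb] + 1L)))
    }
    S4Vectors::mcols(variants)$context3 <- ctx
    variants
}

#' Count variants into the 96-class signature
#'
#' Every classifiable variant is counted in exactly one class; variants with
#' undetermined context (e.g. containing `N`) are excluded and counted in
#' `metadata$n_unclassifiable`. The count vector is invariant under
#' reverse-complement rewriting of the input (strand collapse).
#'
#' @param variants `GRanges` of filtered SNVs with `ref`, `alt` and
#'   `context3` columns (see [addTrinucleotideContext()]); a `reference` may
#'   be supplied to fill missing contexts.
#' @param reference Optional reference (see [addTrinucleotideContext()]).
#' @return A [SignatureCounts-class].
#' @export
countSignature <- function(variants, reference = NULL) {
    mc <- S4Vectors::mcols(variants)
    if (is.null(mc$context3) && !is.null(reference))
        variants <- addTrinucleotideContext(variants, reference)
    mc <- S4Vectors::mcols(variants)
    lab <- classify96(mc$ref, mc$alt, mc$context3)
    counts <- table(factor(lab, levels = sbsClasses()))
    sig <- new("SignatureCounts",
               counts = setNames(as.integer(counts), sbsClasses()),
               total = sum(as.integer(counts)))
    sig
}

#' Fraction of mutations at dipyrimidine sites
#'
#' The fraction of classifiable variants whose 5' or 3' neighbor on the
#' pyrimidine strand is also a pyrimidine (C or T) -- the substrate of
#' UV-induced lesions such as cyclobutane pyrimidine dimers. For variants
#' drawn uniformly over the 96 classes the expected value is 3/4.
#'
#' @inheritParams countSignature
#' @return A single numeric in `[0, 1]`, or `NA` (with a warning) when no
#'   variant is classifiable.
#' @export
dipyrimidineFraction <- function(variants, reference = NULL) {
    mc <- S4Vectors::mcols(variants)
    if (is.null(mc$context3) && !is.null(reference))
        variants <- addTrinucleotideContext(variants, reference)
    mc <- S4Vectors::mcols(variants)
    lab <- classify96(mc$ref, mc$alt, mc$context3)
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L) {
        warning("no classifiable variants; dipyrimidine fraction undefined")
        return(NA_real_)
    }
    five <- substr(lab, 1L, 1L)
    three <- substr(lab, 7L, 7L)
    mean(five %in% c("C", "T") | three %in% c("C", "T"))
}

#' Write a 96-class signature as TSV
#'
#' Emits comment lines with the total and (when supplied) the dipyrimidine
#' fraction, a header, and 96 `class<TAB>count` rows in canonical order.
#'
#' @param sig A [SignatureCounts-class].
#' @param path Output path.
#' @param dipyrimidine Optional precomputed dipyrimidine fraction.
#' @return `path`, invisibly.
#' @export
writeSignatureTsv <- function(sig, path, dipyrimidine = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# total\t%d", sigTotal(sig)), con)
    if (!is.null(dipyrimidine))
        writeLines(sprintf("# dipyrimidine_fraction\t%.6f", dipyrimidine),
                   con)
    writeLines("class\tcount", con)
    writeLines(sprintf("%s\t%d", names(sigCounts(sig)), sigCounts(sig)),
               con)
    invisible(path)
}
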
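## Central S4 data objects. Exon/intron coordinates are GRanges (1-based,
## closed); read-pair and variant coordinates follow the same convention.

#' Gene models as per-gene exon unions
#'
#' A `GeneModelSet` stores, for each gene symbol, the union of its exons over
#' all isoforms as a sorted, disjoint [GenomicRanges::GRanges]. Introns are the
#' gaps between consecutive exons and are derived, never stored. Detection of
#' retrocopies only ever operates on genes with at least two exons (a gene
#' without introns cannot lose them).
#'
#' @slot exons A named [GenomicRanges::GRangesList]; one element per gene
#'   symbol, each a sorted disjoint set of exon ranges on one chromosome and
#'   strand.
#'
#' @seealso [readGeneModels()], [introns()], [nExons()]
#' @export
setClass("GeneModelSet", representation(exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    ex <- object@exons
    if (length(ex) == 0L) return("no gene models")
    if (is.null(names(ex)) || anyDuplicated(names(ex)) || any(names(ex) == ""))
        return("gene symbols must be unique and non-empty")
    n <- S4Vectors::elementNROWS(ex)
    if (any(n < 1L)) return("each gene must have at least one exon")
    flat <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), n)
    if (any(vapply(split(as.character(seqnames(flat)), grp),
                   function(x) length(unique(x)), 1L) != 1L))
        return("exons of one gene must share a chromosome")
    st <- start(flat); en <- end(flat)
    same <- grp[-length(grp)] == grp[-1L]
    if (any(same & (st[-1L] <= en[-length(en)])))
        return("exons of one gene must be sorted and disjoint")
    TRUE
})

#' Mapped read pairs with ostensible template length
#'
#' A `ReadPairSet` holds one row per primary read pair with both mates mapped
#' to the same chromosome: mate reference spans, mapping qualities, and the
#' ostensible template length, i.e. the reference-coordinate span
#' `max(end) - min(start) + 1` of the two mates. The span is recomputed from
#' mate coordinates, never copied from the SAM TLEN column, so it is
#' aligner-independent. For pairs derived from an intronless retrocopy the
#' span is inflated by every intron between the mates' source exons.
#'
#' @slot pairs A [S4Vectors::DataFrame] with columns `sample_id`,
#'   `fragment_id`, `chrom`, `m1_start`, `m1_end`, `m1_mapq`, `m2_start`,
#'   `m2_end`, `m2_mapq`, `tlen`, `proper_orientation`.
#' @slot log Named list of parse counters (records read, pairs emitted,
#'   records dropped and why).
#'
#' @seealso [readSamPairs()], [filterPairs()]
#' @export
setClass("ReadPairSet", representation(pairs = "DataFrame", log = "list"))

setValidity("ReadPairSet", function(object) {
    p <- object@pairs
    need <- c("sample_id", "fragment_id", "chrom", "m1_start", "m1_end",
              "m1_mapq", "m2_start", "m2_end", "m2_mapq", "tlen",
              "proper_orientation")
    if (!all(need %in% colnames(p)))
        return(paste("missing columns:",
                     paste(setdiff(need, colnames(p)), collapse = ", ")))
    if (nrow(p) == 0L) return(TRUE)
    if (any(p$m1_end < p$m1_start) || any(p$m2_end < p$m2_start))
        return("mate end before start")
    mq <- c(p$m1_mapq, p$m2_mapq)
    if (any(mq < 0L | mq > 255L)) return("mapq outside [0, 255]")
    span <- pmax(p$m1_end, p$m2_end) - pmin(p$m1_start, p$m2_start) + 1L
    if (any(p$tlen != span))
        return("tlen does not equal the reference span of the mates")
    TRUE
})

#' Detection thresholds for retrocopy calling
#'
#' Defaults follow the reference analysis: both mates with mapping quality at
#' least 20, ostensible template length at least 1000 bp, an exon counts as
#' supported when at least 2 read ends overlap it ("more than 1 read per
#' exon"), and a gene is called when at least 3 discrete exons are supported
#' ("spanning more than 2 discrete exons").
#'
#' @slot min_mapq Minimum mapping quality, applied to both mates.
#' @slot min_tlen Minimum ostensible template length in bp.
#' @slot min_supported_exons Minimum number of supported exons per candidate
#'   (at least 2; detection is restricted to intron-bearing genes).
#' @slot min_reads_per_exon Minimum read ends overlapping an exon for the exon
#'   to count as supported.
#' @slot recurrence_fraction Fraction of cohort samples at or above which a
#'   gene is flagged as a reference relic (an intronless paralog missing from
#'   the reference assembly rather than a somatic event); default 1.
#'
#' @seealso [detectionParams()]
#' @export
setClass("DetectionParams", representation(
    min_mapq = "integer", min_tlen = "integer",
    min_supported_exons = "integer", min_reads_per_exon = "integer",
    recurrence_fraction = "numeric"))

setValidity("DetectionParams", function(object) {
    if (object@min_mapq < 0L || object@min_tlen < 0L ||
        object@min_reads_per_exon < 0L)
        return("thresholds must be non-negative")
    if (object@min_supported_exons < 2L)
        return("min_supported_exons must be >= 2 (intron-bearing genes only)")
    if (object@recurrence_fraction <= 0 || object@recurrence_fraction > 1)
        return("recurrence_fraction must be in (0, 1]")
    TRUE
})

#' @describeIn DetectionParams-class Constructor with reference defaults.
#' @param min_mapq,min_tlen,min_supported_exons,min_reads_per_exon,recurrence_fraction
#'   See the corresponding slots.
#' @return A `DetectionParams` object.
#' @export
detectionParams <- function(min_mapq = 20L, min_tlen = 1000L,
                            min_supported_exons = 3L,
                            min_reads_per_exon = 2L,
                            recurrence_fraction = 1.0) {
    new("DetectionParams",
        min_mapq = as.integer(min_mapq), min_tlen = as.integer(min_tlen),
        min_supported_exons = as.integer(min_supported_exons),
        min_reads_per_exon = as.integer(min_reads_per_exon),
        recurrence_fraction = as.numeric(recurrence_fraction))
}

#' 96-class single-base-substitution signature counts
#'
#' Counts of somatic single-nucleotide substitutions over the 96 classes
#' defined by the substitution expressed on the pyrimidine strand (C>A, C>G,
#' C>T, T>A, T>C, T>G) and the two flanking reference bases. Class labels have
#' the form `X[R>A]Y`.
#'
#' @slot counts Named non-negative integer vector over exactly the 96 labels
#'   of [sbsClasses()], in canonical order.
#' @slot total Sum of `counts` (the number of classifiable variants).
#'
#' @seealso [countSignature()], [sbsClasses()]
#' @export
setClass("SignatureCounts",
         representation(counts = "integer", total = "integer"))

setValidity("SignatureCounts", function(object) {
    if (length(object@counts) != 96L ||
        !identical(names(object@counts), sbsClasses()))
        return("counts must be named by the 96 canonical classes")
    if (any(object@counts < 0L)) return("negative count")
    if (sum(object@counts) != object@total)
        return("total does not equal the sum of counts")
    TRUE
})

#' Cohort presence/absence matrix of retrocopy candidates
#'
#' A `RetroCohort` extends [SummarizedExperiment::SummarizedExperiment]: one
#' logical assay `present` with genes as rows and samples as columns, and
#' column metadata `sample_id`, `cell_type` (`"parental"` or `"iPSC"`) and
#' `donor_id`. Row metadata carries the source chromosome of each gene and a
#' `recurrent_relic` flag once [flagRecurrent()] has run.
#'
#' @seealso [buildCohortMatrix()], [exclusiveCounts()], [ipscMinusParent()],
#'   [clusterSamples()]
#' @export
setClass("RetroCohort", contains = "SummarizedExperiment")

setValidity("RetroCohort", function(object) {
    if (!"present" %in% SummarizedExperiment::assayNames(object))
        return("assay 'present' missing")
    m <- assay(object, "present")
    if (!is.logical(m)) return("assay 'present' must be logical")
    if (nrow(m) > 0L && any(rowSums(m) == 0L))
        return("every gene row must be present in at least one sample")
    need <- c("sample_id", "cell_type", "donor_id")
    if (!all(need %in% colnames(colData(object))))
        return("colData needs sample_id, cell_type, donor_id")
    if (!all(colData(object)$cell_type %in% c("parental", "iPSC")))
        return("cell_type must be 'parental' or 'iPSC'")
    TRUE
})

#' Result of read-backed phasing of two variants
#'
#' Fragments covering both loci are classified by the alleles they carry:
#' alternate at the first variant only, at the second only, at both, or at
#' neither. Two heterozygous variants lie in *trans* (compound heterozygous)
#' when fragments carry one alternate allele or the other but never both; in
#' *cis* when fragments carry either both alternates or neither.
#'
#' @slot n_A_only,n_B_only,n_both,n_neither Fragment counts per class.
#' @slot verdict One of `"trans"`, `"cis"`, `"ambiguous"`.
#' @slot min_fragments Evidence threshold used for the verdict.
#'
#' @seealso [phaseTwoVariants()]
#' @export
setClass("PhaseCall", representation(
    n_A_only = "integer", n_B_only = "integer", n_both = "integer",
    n_neither = "integer", verdict = "character",
    min_fragments = "integer"))

setValidity("PhaseCall", function(object) {
    k <- c(object@n_A_only, object@n_B_only, object@n_both, object@n_neither)
    if (any(k < 0L)) return("negative fragment count")
    if (!object@verdict %in% c("trans", "cis", "ambiguous"))
        return("verdict must be trans, cis or ambiguous")
    TRUE
})

#' Configuration of the synthetic exome generator
#'
#' Defaults emulate the sequencing design the detector targets: 101-bp
#' paired-end reads (101-cycle Illumina chemistry) with fragment sizes of
#' 300 +/- 50 bp, genes with short exons separated by introns long enough that
#' a retrocopy-derived pair bridging adjacent exons exceeds the 1000-bp
#' ostensible-template-length threshold while ordinary genomic fragments never
#' do.
#'
#' @slot seed Integer seed; all outputs are deterministic given the seed.
#' @slot n_genes Number of genes placed on the synthetic chromosome.
#' @slot exon_count_range,exon_length_range,intron_length_range Integer ranges
#'   (min, max) for exons per gene and exon/intron lengths in bp.
#' @slot read_length Read length in bp (default 101).
#' @slot insert_mean,insert_sd Fragment-size distribution in bp (default
#'   300/50).
#' @slot exonic_coverage Target mean exonic read-end depth.
#' @slot retrocopy_genes Symbols of genes carrying a spiked retrocopy.
#' @slot retrocopy_fraction Fraction of cells carrying each event in `[0, 1]`;
#'   1 models a clonal iPSC line, small values model a heterogeneous parental
#'   fibroblast bulk.
#' @slot error_rate Uniform per-base substitution rate for simulated reads.
#' @slot n_snvs Number of somatic SNVs planted in the iPSC member of a
#'   simulated VCF pair.
#' @slot signature_profile Probability vector over the 96 classes (sums to 1).
#'
#' @seealso [simulationConfig()], [simulateGenome()], [simulateSample()]
#' @export
setClass("SimulationConfig", representation(
    seed = "integer", n_genes = "integer",
    exon_count_range = "integer", exon_length_range = "integer",
    intron_length_range = "integer", read_length = "integer",
    insert_mean = "numeric", insert_sd = "numeric",
    exonic_coverage = "numeric", retrocopy_genes = "character",
    retrocopy_fraction = "numeric", error_rate = "numeric",
    n_snvs = "integer", signature_profile = "numeric"))

setValidity("SimulationConfig", function(object) {
    rng <- function(r) length(r) == 2L && r[1] > 0L && r[2] >= r[1]
    if (!rng(object@exon_count_range) || !rng(object@exon_length_range) ||
        !rng(object@intron_length_range))
        return("ranges must be positive (min, max) pairs")
    if (object@retrocopy_fraction < 0 || object@retrocopy_fraction > 1)
        return("retrocopy_fraction must be in [0, 1]")
    if (object@read_length < 1L) return("read_length must be positive")
    if (length(object@signature_profile) != 96L ||
        abs(sum(object@signature_profile) - 1) > 1e-8 ||
        any(object@signature_profile < 0))
        return("signature_profile must be 96 non-negative values summing to 1")
    TRUE
})
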
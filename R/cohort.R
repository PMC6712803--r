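## Multi-sample comparison of retrocopy candidates: presence/absence matrix,
## reference-relic flagging, exclusive counts, iPSC-minus-parent differences,
## per-chromosome source counts and hierarchical clustering.

#' Build the cohort presence/absence matrix
#'
#' Rows are the union of candidate gene symbols over all samples, columns the
#' samples; an entry is `TRUE` when the gene was called in that sample. Sample
#' metadata (parental vs iPSC, donor) is preserved in the column data and the
#' source chromosome of each gene in the row data.
#'
#' @param per_sample_candidates Named list (names = sample ids) of candidate
#'   tables from [detectSample()] / [callCandidates()].
#' @param sample_info data.frame with columns `sample_id`, `cell_type`
#'   (`"parental"` or `"iPSC"`) and `donor_id`, one row per sample.
#' @return A [RetroCohort-class]. Zero candidate genes anywhere gives a 0-row
#'   object with a warning.
#' @export
buildCohortMatrix <- function(per_sample_candidates, sample_info) {
    ids <- names(per_sample_candidates)
    if (is.null(ids) || anyDuplicated(ids))
        stop("per_sample_candidates must be uniquely named by sample id")
    if (!all(ids %in% sample_info$sample_id))
        stop("sample_info lacks rows for: ",
             paste(setdiff(ids, sample_info$sample_id), collapse = ", "))
    if (anyDuplicated(sample_info$sample_id))
        stop("duplicate sample ids in sample_info")
    sample_info <- sample_info[match(ids, sample_info$sample_id), ,
                               drop = FALSE]
    genes <- sort(unique(unlist(lapply(per_sample_candidates,
                                       function(x) x$gene))))
    if (length(genes) == 0L)
        warning("no candidate genes in any sample; 0-row matrix")
    m <- matrix(FALSE, nrow = length(genes), ncol = length(ids),
                dimnames = list(genes, ids))
    chrom <- setNames(rep(NA_character_, length(genes)), genes)
    for (s in ids) {
        cand <- per_sample_candidates[[s]]
        m[cand$gene, s] <- TRUE
        chrom[cand$gene] <- cand$chrom
    }
    se <- SummarizedExperiment(
        assays = list(present = m),
        rowData = DataFrame(chrom = unname(chrom),
                            recurrent_relic = rep(FALSE, length(genes)),
                            row.names = genes),
        colData = DataFrame(sample_id = ids,
                            cell_type = sample_info$cell_type,
                            donor_id = sample_info$donor_id,
                            row.names = ids))
    new("RetroCohort", se)
}

#' Flag genes recurring across the cohort as reference relics
#'
#' A gene detected in at least `recurrence_fraction` of all samples (default:
#' every sample) is flagged `recurrent_relic`: a hit in all samples of a
#' cohort is far more plausibly an intronless paralog missing from the
#' reference assembly than independent somatic events in every line.
#'
#' @param cohort A [RetroCohort-class].
#' @param params A [DetectionParams-class]; only `recurrence_fraction` is
#'   used.
#' @return The cohort with updated row data; [relicGenes()] lists the flagged
#'   symbols.
#' @export
flagRecurrent <- function(cohort, params = detectionParams()) {
    m <- assay(cohort, "present")
    frac <- rowSums(m) / ncol(m)
    SummarizedExperiment::rowData(cohort)$recurrent_relic <-
        frac >= params@recurrence_fraction
    cohort
}

#' @rdname flagRecurrent
#' @export
relicGenes <- function(cohort) {
    rd <- SummarizedExperiment::rowData(cohort)
    rownames(cohort)[rd$recurrent_relic]
}

.presence <- function(cohort, exclude_relics) {
    m <- assay(cohort, "present")
    if (exclude_relics) {
        rd <- SummarizedExperiment::rowData(cohort)
        m <- m[!rd$recurrent_relic, , drop = FALSE]
    }
    m
}

#' Count genes found in exactly one sample
#'
#' For each sample, the number of (non-relic) genes present in that sample
#' and no other. A gene shared by two or more samples contributes to none.
#'
#' @param cohort A [RetroCohort-class].
#' @param exclude_relics Drop relic-flagged genes first (default `TRUE`).
#' @return Named integer vector over samples.
#' @export
exclusiveCounts <- function(cohort, exclude_relics = TRUE) {
    m <- .presence(cohort, exclude_relics)
    excl <- m & (rowSums(m) == 1L)
    setNames(as.integer(colSums(excl)), colnames(m))
}

#' Per-donor iPSC-minus-parental candidate counts
#'
#' For every donor (and every iPSC line when a donor has several), the number
#' of candidate genes in the iPSC sample minus the number in the matched
#' parental sample. Because an iPSC line is clonal, somatic events hidden in
#' the heterogeneous parental bulk surface in the iPSC, so positive values
#' are the expected direction; negative values are allowed. Donors lacking
#' one of the two cell types are skipped with a warning.
#'
#' @param cohort A [RetroCohort-class].
#' @param exclude_relics Drop relic-flagged genes first (default `TRUE`).
#' @return data.frame with columns `donor_id`, `ipsc_sample`,
#'   `parental_sample`, `n_ipsc`, `n_parental`, `difference`.
#' @export
ipscMinusParent <- function(cohort, exclude_relics = TRUE) {
    m <- .presence(cohort, exclude_relics)
    cd <- colData(cohort)
    totals <- colSums(m)
    out <- list()
    for (d in unique(cd$donor_id)) {
        ip <- cd$sample_id[cd$donor_id == d & cd$cell_type == "iPSC"]
        pa <- cd$sample_id[cd$donor_id == d & cd$cell_type == "parental"]
        if (length(ip) == 0L || length(pa) == 0L) {
            warning("donor ", d, " lacks an iPSC or parental sample; skipped")
            next
        }
        for (i in ip) {
            out[[length(out) + 1L]] <- data.frame(
                donor_id = d, ipsc_sample = i, parental_sample = pa[1L],
                n_ipsc = unname(totals[i]), n_parental = unname(totals[pa[1L]]),
                difference = unname(totals[i] - totals[pa[1L]]))
        }
    }
    if (length(out) == 0L)
        return(data.frame(donor_id = character(0), ipsc_sample = character(0),
                          parental_sample = character(0), n_ipsc = integer(0),
                          n_parental = integer(0), difference = integer(0)))
    do.call(rbind, out)
}

#' Candidate counts per source chromosome and sample
#'
#' Counts candidates by the chromosome of their SOURCE gene (the locus the
#' retrocopy's reads map back to; the integration site is not observable from
#' source-locus evidence). Row sums over chromosomes equal per-sample
#' candidate totals.
#'
#' @param cohort A [RetroCohort-class].
#' @param exclude_relics Drop relic-flagged genes first (default `TRUE`).
#' @return Integer matrix samples x chromosomes.
#' @export
chromosomeCounts <- function(cohort, exclude_relics = TRUE) {
    m <- .presence(cohort, exclude_relics)
    rd <- SummarizedExperiment::rowData(cohort)
    chrom <- setNames(rd$chrom, rownames(cohort))[rownames(m)]
    chroms <- sort(unique(chrom))
    out <- matrix(0L, nrow = ncol(m), ncol = length(chroms),
                  dimnames = list(colnames(m), chroms))
    for (s in colnames(m)) {
        tab <- table(chrom[m[, s]])
        out[s, names(tab)] <- as.integer(tab)
    }
    out
}

#' Hierarchically cluster samples on the presence matrix
#'
#' Samples are clustered on their boolean candidate profiles with Jaccard
#' distance (base `dist(method = "binary")`) and average-linkage
#' agglomeration by default. Identical columns merge at height zero; leaf
#' order is deterministic for a fixed input and invariant to row permutation
#' of the matrix.
#'
#' @param cohort A [RetroCohort-class] with at least 2 samples and 1 gene.
#' @param distance `dist()` method for binary profiles (default
#'   `"binary"` = Jaccard).
#' @param linkage `hclust()` agglomeration method (default `"average"`).
#' @return An `hclust` object; attributes `distance` and `linkage` record the
#'   choices, attribute `dist` the pairwise distance matrix.
#' @export
clusterSamples <- function(cohort, distance = "binary",
                           linkage = "average") {
    m <- assay(cohort, "present")
    if (ncol(m) < 2L) stop("need at least 2 samples to cluster")
    if (nrow(m) < 1L) stop("need at least 1 gene row to cluster")
    d <- dist(t(m * 1L), method = distance)
    d[is.na(d)] <- 0  # two all-absent profiles are identical
    hc <- hclust(d, method = linkage)
    attr(hc, "distance") <- distance
    attr(hc, "linkage") <- linkage
    attr(hc, "dist") <- d
    hc
}

#' Write all cohort reports
#'
#' Emits `matrix.tsv` (presence matrix with relic flags), `exclusive.tsv`,
#' `subtraction.tsv`, `chrom_counts.tsv` and `dendrogram.nwk` (Newick) into
#' a directory.
#'
#' @param cohort A [RetroCohort-class].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohortReports <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- assay(cohort, "present")
    rd <- SummarizedExperiment::rowData(cohort)
    mt <- data.frame(gene = rownames(cohort), chrom = rd$chrom,
                     recurrent_relic = rd$recurrent_relic,
                     as.data.frame(m * 1L, check.names = FALSE))
    write.table(mt, file.path(dir, "matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ex <- exclusiveCounts(cohort)
    write.table(data.frame(sample = names(ex), exclusive_genes = ex),
                file.path(dir, "exclusive.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ipscMinusParent(cohort), file.path(dir, "subtraction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cc <- chromosomeCounts(cohort)
    write.table(data.frame(sample = rownames(cc), cc, check.names = FALSE),
                file.path(dir, "chrom_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (ncol(cohort) >= 2L && nrow(cohort) >= 1L) {
        hc <- clusterSamples(cohort)
        ape::write.tree(ape::as.phylo(hc),
                        file.path(dir, "dendrogram.nwk"))
    }
    invisible(dir)
}
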
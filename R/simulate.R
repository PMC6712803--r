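## Deterministic synthetic-data generator. Emulates (a) exome read pairs from
## intronless retrocopies, whose mates map back to distinct exons of the
## source gene with intron-inflated ostensible template length, (b) ordinary
## concordant exome pairs, (c) parent/iPSC VCF pairs whose somatic SNVs follow
## a chosen 96-class profile, and (d) read sets for cis/trans phasing.

#' UV-like default signature profile
#'
#' A C>T-dominated 96-class profile: 60% of mass on C>T classes with a 5'
#' pyrimidine (the dipyrimidine-context classes enriched under defective
#' nucleotide excision repair), 25% on the remaining C>T classes, and 15%
#' spread uniformly over the C>A and T>C blocks. 48 classes carry zero mass.
#'
#' @return Numeric vector of 96 probabilities summing to 1, named by
#'   [sbsClasses()].
#' @export
uvSignatureProfile <- function() {
    cls <- sbsClasses()
    p <- setNames(numeric(96L), cls)
    ct <- grepl("\\[C>T\\]", cls)
    dipyr5 <- ct & substr(cls, 1L, 1L) %in% c("C", "T")
    p[dipyr5] <- 0.60 / sum(dipyr5)
    p[ct & !dipyr5] <- 0.25 / sum(ct & !dipyr5)
    bg <- grepl("\\[C>A\\]", cls) | grepl("\\[T>C\\]", cls)
    p[bg] <- 0.15 / sum(bg)
    p
}

#' @describeIn SimulationConfig-class Constructor with study-like defaults:
#'   101-bp paired-end reads, 300 +/- 50 bp fragments, 100x exonic coverage,
#'   20 genes of 2-8 exons (120-400 bp) separated by 1200-3000 bp introns,
#'   1000 somatic SNVs from the UV-like profile.
#' @param seed,n_genes,exon_count_range,exon_length_range,intron_length_range,read_length,insert_mean,insert_sd,exonic_coverage,retrocopy_genes,retrocopy_fraction,error_rate,n_snvs,signature_profile
#'   See the corresponding slots.
#' @return A `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, n_genes = 20L,
                             exon_count_range = c(2L, 8L),
                             exon_length_range = c(120L, 400L),
                             intron_length_range = c(1200L, 3000L),
                             read_length = 101L, insert_mean = 300,
                             insert_sd = 50, exonic_coverage = 100,
                             retrocopy_genes = character(0),
                             retrocopy_fraction = 1.0, error_rate = 0,
                             n_snvs = 1000L,
                             signature_profile = uvSignatureProfile()) {
    new("SimulationConfig", seed = as.integer(seed),
        n_genes = as.integer(n_genes),
        exon_count_range = as.integer(exon_count_range),
        exon_length_range = as.integer(exon_length_range),
        intron_length_range = as.integer(intron_length_range),
        read_length = as.integer(read_length),
        insert_mean = as.numeric(insert_mean),
        insert_sd = as.numeric(insert_sd),
        exonic_coverage = as.numeric(exonic_coverage),
        retrocopy_genes = retrocopy_genes,
        retrocopy_fraction = as.numeric(retrocopy_fraction),
        error_rate = as.numeric(error_rate), n_snvs = as.integer(n_snvs),
        signature_profile = as.numeric(signature_profile))
}

.randSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference with gene models
#'
#' Places `n_genes` non-overlapping genes on one synthetic chromosome
#' (`chrS`), with exon counts and exon/intron lengths drawn from the
#' configured ranges and intergenic gaps of 2-4 kb. Deterministic for a
#' fixed seed (byte-identical FASTA on reruns).
#'
#' @param config A [SimulationConfig-class].
#' @return List with elements `reference` ([Biostrings::DNAStringSet]),
#'   `genes` ([GeneModelSet-class]) and `truth` (data.frame of per-gene
#'   structure: symbol, n_exons, cdna_length).
#' @export
simulateGenome <- function(config) {
    set.seed(config@seed)
    ecr <- config@exon_count_range
    elr <- config@exon_length_range
    ilr <- config@intron_length_range
    cursor <- 1L
    exon_list <- list()
    for (i in seq_len(config@n_genes)) {
        gap <- sample(2000:4000, 1L)
        cursor <- cursor + gap
        n_ex <- sample(ecr[1L]:ecr[2L], 1L)
        ex_len <- sample(elr[1L]:elr[2L], n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L) {
            sample(ilr[1L]:ilr[2L], n_ex - 1L, replace = TRUE)
        } else integer(0)
        starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
        ends <- starts + ex_len - 1L
        exon_list[[sprintf("GENE%02d", i)]] <-
            GRanges("chrS", IRanges(starts, ends), strand = "+")
        cursor <- ends[n_ex] + 1L
    }
    chrom_len <- cursor + 2000L
    genes <- GeneModelSet(GRangesList(exon_list))
    reference <- DNAStringSet(setNames(.randSeq(chrom_len), "chrS"))
    truth <- data.frame(
        symbol = geneSymbols(genes),
        n_exons = unname(nExons(genes)),
        cdna_length = vapply(as.list(exons(genes)),
                             function(g) sum(width(g)), 1L))
    list(reference = reference, genes = genes, truth = truth)
}

#' Map a cDNA interval to its genomic footprint
#'
#' Converts a (1-based, closed) interval on a gene's spliced cDNA to the
#' corresponding genomic interval(s) via cumulative exon offsets. An
#' interval crossing an exon junction returns one range per exon touched.
#'
#' @param gene Exons of one gene: a sorted `GRanges` (one element of
#'   `exons(GeneModelSet)`).
#' @param cdna_interval Integer `c(start, end)`, 1-based closed, within
#'   `[1, sum(width(gene))]`.
#' @return `GRanges` of genomic blocks, in cDNA order.
#' @export
mapCdnaToGenome <- function(gene, cdna_interval) {
    w <- width(gene)
    total <- sum(w)
    s <- cdna_interval[1L]; e <- cdna_interval[2L]
    if (s < 1L || e > total || e < s)
        stop("cDNA interval [", s, ", ", e, "] outside [1, ", total, "]")
    cum_end <- cumsum(w)
    cum_start <- cum_end - w + 1L
    hit <- which(cum_end >= s & cum_start <= e)
    GRanges(as.character(seqnames(gene)[1L]),
            IRanges(start = start(gene)[hit] + pmax(s, cum_start[hit]) -
                        cum_start[hit],
                    end = start(gene)[hit] + pmin(e, cum_end[hit]) -
                        cum_start[hit]),
            strand = strand(gene)[1L])
}

## One mate (cDNA interval) -> major-block alignment. Junction-crossing
## mates are truncated to their largest genomic block, with the discarded
## cDNA bases recorded as soft clips (a DNA read mapper does not produce
## spliced alignments from retrocopy reads). Plain-arithmetic equivalent of
## mapCdnaToGenome (kept S4-free: called once per simulated mate).
.mateAlignment <- function(geom, cdna_lo, cdna_hi) {
    hit <- which(geom$cum_end >= cdna_lo & geom$cum_start <= cdna_hi)
    blo <- pmax(cdna_lo, geom$cum_start[hit])
    bhi <- pmin(cdna_hi, geom$cum_end[hit])
    bw <- bhi - blo + 1L
    j <- which.max(bw)  # ties -> first
    lclip <- if (j > 1L) sum(bw[seq_len(j - 1L)]) else 0L
    rclip <- sum(bw) - lclip - bw[j]
    cig <- paste0(if (lclip > 0L) paste0(lclip, "S") else "",
                  bw[j], "M",
                  if (rclip > 0L) paste0(rclip, "S") else "")
    k <- hit[j]
    gs <- geom$gstart[k] + blo[j] - geom$cum_start[k]
    list(start = gs, end = gs + bw[j] - 1L, cigar = cig,
         aligned_cdna_lo = cdna_lo + lclip,
         aligned_cdna_hi = cdna_hi - rclip)
}

#' Simulate read pairs from an intronless retrocopy
#'
#' Fragments of length ~ Normal(`insert_mean`, `insert_sd`) are sampled
#' along the gene's cDNA; each mate's genomic coordinates come from
#' [mapCdnaToGenome()], so a pair whose mates derive from different exons is
#' emitted with an ostensible template length equal to its aligned cDNA span
#' plus every intron lying between the mates' genomic footprints.
#'
#' @param gene Exons of the source gene (`GRanges`, at least 2 ranges).
#' @param config A [SimulationConfig-class].
#' @param n_pairs Number of pairs; default targets
#'   `exonic_coverage * retrocopy_fraction` over the cDNA.
#' @param id_prefix Fragment-name prefix.
#' @return data.frame of SAM records (see [writeSamFile()]) with truth
#'   columns `frag_len`, `aligned_cdna_lo`, `aligned_cdna_hi` attached as
#'   attribute `truth` (one row per pair).
#' @export
simulateRetrocopyPairs <- function(gene, config, n_pairs = NULL,
                                   id_prefix = "rc") {
    if (length(gene) < 2L) stop("retrocopy source gene must have >= 2 exons")
    rl <- config@read_length
    cdna_len <- sum(width(gene))
    if (is.null(n_pairs))
        n_pairs <- max(1L, round(config@exonic_coverage *
                                 config@retrocopy_fraction * cdna_len /
                                 (2 * rl)))
    frag <- integer(0)
    while (length(frag) < n_pairs) {
        f <- as.integer(round(rnorm(n_pairs, config@insert_mean,
                                    config@insert_sd)))
        f <- f[f >= rl & f <= cdna_len]  # too-long fragments resampled
        frag <- c(frag, f)
    }
    frag <- frag[seq_len(n_pairs)]
    s <- vapply(frag, function(f)
        sample.int(cdna_len - f + 1L, 1L), 1L)
    w <- width(gene)
    geom <- list(cum_end = cumsum(w), cum_start = cumsum(w) - w + 1L,
                 gstart = start(gene))
    chrom <- as.character(seqnames(gene)[1L])
    p1 <- p2 <- tl <- alo <- ahi <- integer(n_pairs)
    cg1 <- cg2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
        a1 <- .mateAlignment(geom, s[i],
                             min(s[i] + rl - 1L, s[i] + frag[i] - 1L))
        a2 <- .mateAlignment(geom, max(s[i] + frag[i] - rl, s[i]),
                             s[i] + frag[i] - 1L)
        p1[i] <- a1$start; p2[i] <- a2$start
        cg1[i] <- a1$cigar; cg2[i] <- a2$cigar
        tl[i] <- max(a1$end, a2$end) - min(a1$start, a2$start) + 1L
        alo[i] <- a1$aligned_cdna_lo; ahi[i] <- a2$aligned_cdna_hi
    }
    qn <- paste0(id_prefix, seq_len(n_pairs))
    out <- data.frame(
        qname = rep(qn, each = 2L),
        flag = rep(c(99L, 147L), n_pairs), rname = chrom,
        pos = as.vector(rbind(p1, p2)), mapq = 60L,
        cigar = as.vector(rbind(cg1, cg2)), rnext = "=",
        pnext = as.vector(rbind(p2, p1)),
        tlen = as.vector(rbind(tl, -tl)),
        seq = "*", qual = "*")
    attr(out, "truth") <- data.frame(
        fragment_id = qn, frag_len = frag,
        cdna_lo = s, cdna_hi = s + frag - 1L,
        aligned_cdna_lo = alo, aligned_cdna_hi = ahi, tlen = tl)
    out
}

#' Simulate concordant background exome pairs
#'
#' Null model: contiguous genomic fragments (no intron removal) captured
#' around exons, with the configured insert-size distribution. Their
#' ostensible template length equals the fragment length, so with
#' 300 +/- 50 bp inserts effectively no pair reaches the 1000-bp threshold
#' (a 14-standard-deviation tail).
#'
#' @param genes A [GeneModelSet-class] (capture targets).
#' @param config A [SimulationConfig-class].
#' @param chrom_len Chromosome length (for clamping).
#' @param n_pairs Number of pairs; by default the count is calibrated (via a
#'   pilot draw measuring the on-exon base yield per pair, since captured
#'   fragments spill into flanking introns) so the mean per-base read depth
#'   over the exon union matches `exonic_coverage`.
#' @param id_prefix Fragment-name prefix.
#' @return data.frame of SAM records.
#' @export
simulateBackgroundPairs <- function(genes, config, chrom_len,
                                    n_pairs = NULL, id_prefix = "bg") {
    rl <- config@read_length
    flat <- unlist(exons(genes), use.names = FALSE)
    total_ex <- sum(width(flat))
    chrom <- as.character(seqnames(flat)[1L])
    draw <- function(n) {
        frag <- pmax(2L * rl, round(rnorm(n, config@insert_mean,
                                          config@insert_sd)))
        ## capture: anchor each fragment on an exon base chosen uniformly
        exi <- sample.int(length(flat), n, replace = TRUE,
                          prob = width(flat))
        anchor <- start(flat)[exi] +
            vapply(width(flat)[exi], function(w) sample.int(w, 1L) - 1L,
                   1L)
        fs <- pmax(1L, pmin(anchor - frag %/% 2L, chrom_len - frag))
        list(fs = fs, frag = frag, m2s = fs + frag - rl)
    }
    if (is.null(n_pairs)) {
        pilot <- draw(2000L)
        reads <- GRanges(chrom, IRanges(
            start = c(pilot$fs, pilot$m2s),
            width = rl))
        ov <- findOverlaps(reads, flat)
        yield <- sum(width(IRanges::pintersect(
            granges(reads)[queryHits(ov)], flat[subjectHits(ov)])))
        n_pairs <- max(1L, round(config@exonic_coverage * total_ex /
                                 (yield / 2000)))
    }
    d <- draw(n_pairs)
    qn <- paste0(id_prefix, seq_len(n_pairs))
    data.frame(
        qname = rep(qn, each = 2L),
        flag = rep(c(99L, 147L), n_pairs),
        rname = chrom,
        pos = as.vector(rbind(d$fs, d$m2s)),
        mapq = 60L,
        cigar = paste0(rl, "M"),
        rnext = "=",
        pnext = as.vector(rbind(d$m2s, d$fs)),
        tlen = as.vector(rbind(d$frag, -d$frag)),
        seq = "*", qual = "*")
}

#' Simulate one whole exome sample as SAM
#'
#' Background pairs over all genes plus retrocopy-derived pairs for every
#' gene in `config@retrocopy_genes`, written as one SAM file. Deterministic
#' for fixed `config@seed` (plus `seed_offset`).
#'
#' @param genome Output of [simulateGenome()].
#' @param config A [SimulationConfig-class]; `retrocopy_genes` names the
#'   spiked genes.
#' @param path Output SAM path.
#' @param sample_id Sample name recorded in the read group.
#' @param seed_offset Added to `config@seed` so per-sample streams differ
#'   reproducibly within a cohort.
#' @return Invisibly, a list with `path`, `truth` (per-pair truth records of
#'   the spiked pairs, with a `gene` column) and `n_background`.
#' @export
simulateSample <- function(genome, config, path, sample_id = "sample",
                           seed_offset = 0L) {
    set.seed(config@seed + seed_offset)
    chrom_len <- length(genome$reference[[1L]])
    recs <- simulateBackgroundPairs(genome$genes, config, chrom_len)
    truth <- list()
    for (g in config@retrocopy_genes) {
        if (!g %in% geneSymbols(genome$genes))
            stop("unknown retrocopy gene: ", g)
        rc <- simulateRetrocopyPairs(exons(genome$genes)[[g]], config,
                                     id_prefix = paste0("rc_", g, "_"))
        tr <- attr(rc, "truth")
        tr$gene <- g
        truth[[g]] <- tr
        recs <- rbind(recs, rc)
    }
    writeSamFile(recs, setNames(chrom_len, "chrS"), path,
                 sample_id = sample_id)
    invisible(list(path = path,
                   truth = if (length(truth)) do.call(rbind, truth)
                           else NULL,
                   n_background = sum(startsWith(recs$qname, "bg")) / 2L))
}

#' Simulate a parent/iPSC VCF pair with a known signature
#'
#' Plants `n_snvs` somatic SNVs at reference sites whose trinucleotide
#' matches a class drawn from `signature_profile` (realized on either strand
#' with equal probability), on top of shared germline variants present in
#' both files. To exercise the downstream filters, additional somatic
#' variants are planted with depth below `min_depth` and inside generated
#' structural-exclusion regions (BED).
#'
#' @param genome Output of [simulateGenome()].
#' @param config A [SimulationConfig-class].
#' @param dir Output directory for `parent.vcf`, `ipsc.vcf`,
#'   `exclusion.bed`.
#' @param n_germline,n_lowdepth,n_excluded Counts of shared germline
#'   variants, low-depth somatic decoys and somatic decoys inside excluded
#'   regions.
#' @param min_depth Depth threshold the decoys are built around (default 8).
#' @return Invisibly, list with file paths and `truth` (data.frame: chrom,
#'   pos, ref, alt, class, status in pass/lowdepth/excluded).
#' @export
simulateVariantPair <- function(genome, config, dir, n_germline = 30L,
                                n_lowdepth = 20L, n_excluded = 20L,
                                min_depth = 8L) {
    set.seed(config@seed + 7L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ref <- genome$reference
    chrom <- names(ref)[1L]
    chrseq <- as.character(ref[[1L]])
    chrom_len <- nchar(chrseq)

    ## exclusion regions: two blocks in the second half of the chromosome
    excl <- GRanges(chrom, IRanges(
        start = c(round(chrom_len * 0.55), round(chrom_len * 0.8)),
        width = round(chrom_len * 0.05)))
    rtracklayer::export(excl, file.path(dir, "exclusion.bed"),
                        format = "bed")

    ## index genomic trinucleotide positions once
    triN <- substring(chrseq, seq_len(chrom_len - 2L),
                      seq_len(chrom_len - 2L) + 2L)
    idx <- split(seq_len(chrom_len - 2L) + 1L, triN)  # center positions
    excl_s <- start(excl); excl_e <- end(excl)
    in_excl <- function(p) {
        r <- rep(FALSE, length(p))
        for (k in seq_along(excl_s))
            r <- r | (p >= excl_s[k] & p <= excl_e[k])
        r
    }

    used <- integer(0)
    drawSite <- function(class_label, want_excluded) {
        ## pyrimidine-strand context and alt base from the label
        ctx <- paste0(substr(class_label, 1, 1), substr(class_label, 3, 3),
                      substr(class_label, 7, 7))
        altp <- substr(class_label, 5, 5)
        repeat {
            minus <- runif(1) < 0.5
            g_ctx <- if (minus) .revcompChar(ctx) else ctx
            pool <- idx[[g_ctx]]
            pool <- pool[!pool %in% used & pool > 1L & pool < chrom_len]
            pool <- pool[if (want_excluded) in_excl(pool)
                         else !in_excl(pool)]
            if (length(pool) == 0L) next  # redraw strand / try again
            p <- pool[sample.int(length(pool), 1L)]
            used <<- c(used, p)
            alt <- if (minus) chartr("ACGT", "TGCA", altp) else altp
            return(list(pos = p, ref = substr(chrseq, p, p), alt = alt))
        }
    }

    profile <- config@signature_profile
    classes <- sbsClasses()
    drawClasses <- function(n) {
        classes[sample.int(96L, n, replace = TRUE, prob = profile)]
    }
    mkvar <- function(cl, status) {
        want_excl <- status == "excluded"
        depth <- switch(status,
                        pass = sample(min_depth:(min_depth + 40L), 1L),
                        lowdepth = sample(1:(min_depth - 1L), 1L),
                        excluded = sample(min_depth:(min_depth + 40L), 1L))
        site <- drawSite(cl, want_excl)
        data.frame(chrom = chrom, pos = site$pos, ref = site$ref,
                   alt = site$alt, depth = depth,
                   genotype = if (runif(1) < 0.03) "hom" else "het",
                   class = cl, status = status)
    }
    som <- rbind(
        if (config@n_snvs > 0L)
            do.call(rbind, lapply(drawClasses(config@n_snvs), mkvar,
                                  "pass")),
        if (n_lowdepth > 0L)
            do.call(rbind, lapply(drawClasses(n_lowdepth), mkvar,
                                  "lowdepth")),
        if (n_excluded > 0L)
            do.call(rbind, lapply(drawClasses(n_excluded), mkvar,
                                  "excluded")))
    if (is.null(som))
        som <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          depth = integer(0), genotype = character(0),
                          class = character(0), status = character(0))

    ## germline variants shared by both call sets (random sites)
    germ <- NULL
    if (n_germline > 0L) {
        gp <- sample(setdiff(2:(chrom_len - 1L), used), n_germline)
        used <- c(used, gp)
        gref <- substring(chrseq, gp, gp)
        galt <- vapply(gref, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        germ <- data.frame(chrom = chrom, pos = gp, ref = gref, alt = galt,
                           depth = sample(20:60, n_germline,
                                          replace = TRUE),
                           genotype = sample(c("het", "hom"), n_germline,
                                             replace = TRUE,
                                             prob = c(0.7, 0.3)))
    }
    asGr <- function(d) {
        GRanges(d$chrom, IRanges(d$pos, d$pos),
                ref = d$ref, alt = d$alt, depth = d$depth,
                genotype = d$genotype)
    }
    parent_path <- file.path(dir, "parent.vcf")
    ipsc_path <- file.path(dir, "ipsc.vcf")
    writeVcfFile(if (is.null(germ)) GRanges() else asGr(germ),
                 "parent", parent_path)
    ipsc <- som[, c("chrom", "pos", "ref", "alt", "depth", "genotype")]
    if (!is.null(germ)) ipsc <- rbind(germ, ipsc)
    writeVcfFile(asGr(ipsc), "ipsc", ipsc_path)
    invisible(list(parent = parent_path, ipsc = ipsc_path,
                   exclusion = file.path(dir, "exclusion.bed"),
                   truth = som))
}

#' Simulate read pairs for phasing two variants
#'
#' Builds the two haplotype sequences implied by `configuration` over a
#' random reference (`trans`: the SNV on one homolog, the deletion on the
#' other; `cis`: both on one), then samples fragments alternately from the
#' two haplotypes such that the first mate covers the SNV locus and the
#' second spans the deletion interval. Reads from the deletion haplotype
#' crossing the junction carry a `D` CIGAR operation. At `error_rate` 0 and
#' `configuration = "trans"`, no fragment carries both alternate alleles.
#'
#' @param varA An [snvVariant()].
#' @param varB A [deletionVariant()] on the same chromosome, downstream of
#'   `varA`.
#' @param configuration `"trans"` or `"cis"`.
#' @param coverage Total number of fragments sampled (split evenly between
#'   haplotypes).
#' @param error_rate Per-base substitution rate in the reads.
#' @param seed Random seed.
#' @param path Output SAM path.
#' @param read_length Read length (default 101).
#' @return Invisibly, `path`.
#' @export
simulatePhasingReads <- function(varA, varB,
                                 configuration = c("trans", "cis"),
                                 coverage = 30L, error_rate = 0,
                                 seed = 1L, path, read_length = 101L) {
    configuration <- match.arg(configuration)
    set.seed(seed)
    if (varA$chrom != varB$chrom) stop("variants on different chromosomes")
    if (varA$start >= varB$start)
        stop("varA must lie upstream of varB")
    rl <- read_length
    ds <- varB$start; de <- varB$end; dlen <- de - ds + 1L
    A <- varA$start
    if (ds - A > 3L * rl)
        stop("variants farther apart than the fragment span")
    if (A + rl > ds)
        stop("SNV too close to the deletion for junction-free first mates")
    org <- max(1L, A - 2000L)
    chrom_len <- de + 2000L
    refseq <- .randSeq(chrom_len)
    substrAssign <- function(s, at, value) {
        paste0(substr(s, 1L, at - 1L), value,
               substr(s, at + nchar(value), nchar(s)))
    }
    refseq <- substrAssign(refseq, A, varA$ref)  # plant the SNV ref base
    hapSnv <- substrAssign(refseq, A, varA$alt)
    hapDel <- paste0(substr(refseq, 1L, ds - 1L),
                     substr(refseq, de + 1L, chrom_len))
    hapBoth <- paste0(substr(hapSnv, 1L, ds - 1L),
                      substr(hapSnv, de + 1L, chrom_len))
    haps <- switch(configuration,
                   trans = list(a = list(seq = hapSnv, del = FALSE),
                                b = list(seq = hapDel, del = TRUE)),
                   cis = list(a = list(seq = hapBoth, del = TRUE),
                              b = list(seq = refseq, del = FALSE)))
    addErr <- function(s) {
        if (error_rate <= 0) return(s)
        n <- nchar(s)
        hit <- which(runif(n) < error_rate)
        for (i in hit) {
            b <- sample(setdiff(c("A", "C", "G", "T"),
                                substr(s, i, i)), 1L)
            s <- substrAssign(s, i, b)
        }
        s
    }
    rec <- vector("list", coverage)
    for (i in seq_len(coverage)) {
        h <- haps[[(i - 1L) %% 2L + 1L]]
        s1 <- sample(seq(A - rl + 1L, A), 1L)          # read1 covers the SNV
        r2 <- sample(seq(de + 2L - rl, ds - 1L), 1L)   # read2 spans the del
        ## read1: entirely upstream of the deletion on both haplotypes
        seq1 <- addErr(substr(h$seq, s1, s1 + rl - 1L))
        if (h$del) {
            x <- ds - r2
            cig2 <- paste0(x, "M", dlen, "D", rl - x, "M")
            seq2 <- addErr(substr(h$seq, r2, r2 + rl - 1L))
        } else {
            cig2 <- paste0(rl, "M")
            seq2 <- addErr(substr(h$seq, r2, r2 + rl - 1L))
        }
        span2 <- r2 + rl - 1L + if (h$del) dlen else 0L
        tl <- span2 - s1 + 1L
        rec[[i]] <- data.frame(
            qname = paste0("ph", i), flag = c(99L, 147L),
            rname = varA$chrom, pos = c(s1, r2), mapq = 60L,
            cigar = c(paste0(rl, "M"), cig2), rnext = "=",
            pnext = c(r2, s1), tlen = c(tl, -tl),
            seq = c(seq1, seq2),
            qual = strrep("I", rl))
    }
    writeSamFile(do.call(rbind, rec), setNames(chrom_len, varA$chrom),
                 path)
    invisible(path)
}
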
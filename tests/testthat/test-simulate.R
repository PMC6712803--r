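test_that("genome simulation is deterministic and respects ranges", {
    cfg <- simulationConfig(seed = 1, n_genes = 10,
                            exon_count_range = c(2, 8))
    g1 <- simulateGenome(cfg)
    g2 <- simulateGenome(cfg)
    expect_identical(as.character(g1$reference), as.character(g2$reference))
    expect_identical(g1$truth, g2$truth)
    ## byte-identical FASTA for a fixed seed
    f1 <- tempfile(); f2 <- tempfile()
    Biostrings::writeXStringSet(g1$reference, f1)
    Biostrings::writeXStringSet(g2$reference, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(length(g1$genes), 10L)
    expect_true(all(nExons(g1$genes) >= 2 & nExons(g1$genes) <= 8))
    ## cDNA length is the exon-length sum
    expect_equal(g1$truth$cdna_length,
                 unname(vapply(as.list(exons(g1$genes)),
                               function(e) sum(width(e)), 1L)))
    ## introns within the configured range
    il <- unlist(lapply(as.list(introns(g1$genes)), width))
    expect_true(all(il >= 1200 & il <= 3000))
})

test_that("cDNA mapping matches a base-by-base oracle", {
    gene <- GRanges("chrS", IRanges(c(1001, 1501, 2001),
                                    c(1200, 1700, 2200)), "+")
    oracle <- cdnaMapOracle(gene)  # genomic position of every cDNA base
    ## within one exon
    b1 <- mapCdnaToGenome(gene, c(50, 150))
    expect_equal(start(b1), oracle[50])
    expect_equal(end(b1), oracle[150])
    expect_equal(length(b1), 1L)
    ## crossing the first junction: two blocks
    b2 <- mapCdnaToGenome(gene, c(150, 250))
    expect_equal(length(b2), 2L)
    expect_equal(unlist(Map(seq, start(b2), end(b2)), use.names = FALSE),
                 oracle[150:250])
    ## sweep: every 10-bp window agrees with the oracle exactly
    for (s in seq(1, 591, by = 13)) {
        b <- mapCdnaToGenome(gene, c(s, s + 9))
        expect_equal(unlist(Map(seq, start(b), end(b)),
                            use.names = FALSE), oracle[s:(s + 9)])
    }
    expect_error(mapCdnaToGenome(gene, c(0, 10)), "outside")
    expect_error(mapCdnaToGenome(gene, c(590, 601)), "outside")
})

test_that("retrocopy pair template length obeys the intron identity", {
    cfg <- simulationConfig(seed = 31, n_genes = 6)
    genome <- simulateGenome(cfg)
    sym <- names(which(nExons(genome$genes) >= 4))[1]
    gene <- exons(genome$genes)[[sym]]
    rec <- simulateRetrocopyPairs(gene, cfg, n_pairs = 800)
    tru <- attr(rec, "truth")
    oracle <- cdnaMapOracle(gene)
    ## tlen == genomic span of the aligned cDNA interval, base-by-base
    expect_equal(tru$tlen,
                 oracle[tru$aligned_cdna_hi] -
                     oracle[tru$aligned_cdna_lo] + 1L)
    ## equivalently: tlen - aligned span == introns strictly between
    aligned_span <- tru$aligned_cdna_hi - tru$aligned_cdna_lo + 1L
    intron_between <- vapply(seq_len(nrow(tru)), function(i) {
        gpos <- oracle[tru$aligned_cdna_lo[i]:tru$aligned_cdna_hi[i]]
        sum(diff(gpos) - 1L)
    }, 1L)
    expect_identical(tru$tlen - aligned_span, intron_between)
    ## unclipped pairs: aligned span equals the fragment length
    uncl <- tru$aligned_cdna_lo == tru$cdna_lo &
        tru$aligned_cdna_hi == tru$cdna_hi
    expect_true(any(uncl))
    expect_equal(tru$tlen[uncl] - tru$frag_len[uncl],
                 intron_between[uncl])
    ## a fragment wholly inside one exon has tlen == fragment length
    inside <- intron_between == 0L
    if (any(inside))
        expect_equal(tru$tlen[inside], aligned_span[inside])
})

test_that("background pairs stay concordant at the right depth", {
    cfg <- simulationConfig(seed = 1, n_genes = 8, exonic_coverage = 60)
    genome <- simulateGenome(cfg)
    set.seed(cfg@seed)
    chrom_len <- length(genome$reference[[1]])
    rec <- simulateBackgroundPairs(genome$genes, cfg, chrom_len)
    ## no intron removal: tlen is just the insert, far below 1000
    expect_true(all(abs(rec$tlen) < 1000))
    ## mean exon read depth within 20% of target
    flat <- unlist(exons(genome$genes), use.names = FALSE)
    reads <- GRanges(rec$rname, IRanges(rec$pos, width = 101))
    cov <- GenomicRanges::coverage(reads)[["chrS"]]
    exon_depth <- mean(as.numeric(cov)[unlist(Map(seq, start(flat),
                                                  end(flat)))])
    expect_gt(exon_depth, 0.8 * 60)
    expect_lt(exon_depth, 1.2 * 60)
})

test_that("sample simulation is reproducible byte for byte", {
    cfg <- simulationConfig(seed = 13, n_genes = 5, exonic_coverage = 20,
                            retrocopy_genes = character(0))
    genome <- simulateGenome(cfg)
    s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
    simulateSample(genome, cfg, s1, sample_id = "rep")
    simulateSample(genome, cfg, s2, sample_id = "rep")
    expect_identical(readLines(s1), readLines(s2))
})

test_that("variant-pair simulation plants the profile and the decoys", {
    cfg <- simulationConfig(seed = 3, n_genes = 10, n_snvs = 120,
                            signature_profile =
                                setNames(c(1, rep(0, 95)),
                                         sbsClasses()))
    genome <- simulateGenome(cfg)
    dir <- tempfile()
    vp <- simulateVariantPair(genome, cfg, dir, n_germline = 15,
                              n_lowdepth = 10, n_excluded = 10)
    ## point-mass profile: every passing somatic variant is that class
    expect_true(all(vp$truth$class[vp$truth$status == "pass"] ==
                    sbsClasses()[1]))
    som <- somaticDiff(readVcfSnvs(vp$ipsc), readVcfSnvs(vp$parent))
    expect_equal(length(som), 140L)  # 120 pass + 10 lowdepth + 10 excluded
    filt <- applyVariantFilters(som, signatureFilterParams(
        excluded_regions = vp$exclusion))
    expect_equal(length(filt), 120L)
    sig <- countSignature(addTrinucleotideContext(filt,
                                                  genome$reference))
    expect_equal(unname(sigCounts(sig)[1]), 120L)
    expect_equal(sigTotal(sig), 120L)
    ## zero planted variants: iPSC equals parent plus nothing somatic
    cfg0 <- simulationConfig(seed = 3, n_genes = 10, n_snvs = 0)
    vp0 <- simulateVariantPair(genome, cfg0, tempfile(), n_germline = 15,
                               n_lowdepth = 0, n_excluded = 0)
    som0 <- somaticDiff(readVcfSnvs(vp0$ipsc), readVcfSnvs(vp0$parent))
    expect_equal(length(som0), 0L)
})
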
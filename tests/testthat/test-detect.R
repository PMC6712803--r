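test_that("pair filter applies inclusive thresholds to both mates", {
    ps <- makePairSet("chr1",
                      p1s = c(1001, 1001, 1001),
                      p1e = c(1100, 1100, 1100),
                      q1 = c(20, 19, 60),
                      p2s = c(1901, 4901, 1900),
                      p2e = c(2000, 5000, 1999),
                      q2 = c(20, 60, 60))
    ## tlens: 1000 (kept), 4000 (mapq 19 on one mate), 999 (below)
    kept <- filterPairs(ps, detectionParams())
    expect_equal(pairData(kept)$fragment_id, "f1")
    lg <- parseLog(kept)
    expect_equal(lg$dropped_mapq, 1L)
    expect_equal(lg$dropped_tlen, 1L)
})

test_that("exon support requires both mates exonic and records bridging", {
    gm <- tinyGenes()
    ## f1 bridges exons 1 and 3 of G1; f2 has mate2 in the first intron
    ps <- makePairSet("chr1",
                      p1s = c(1050, 1050), p1e = c(1149, 1149),
                      q1 = 60,
                      p2s = c(2050, 1250), p2e = c(2149, 1349),
                      q2 = 60)
    sup <- assignToGenes(ps, gm)
    expect_named(sup, "G1")
    expect_equal(sup$G1$counts, c(1L, 0L, 1L))
    expect_equal(sup$G1$n_pairs, 1L)
    expect_equal(sup$G1$bridging$exon1, 1L)
    expect_equal(sup$G1$bridging$exon2, 3L)
})

test_that("nested genes both accumulate, matching a brute-force scan", {
    nested <- GeneModelSet(GRangesList(
        OUTER = GRanges("chr1", IRanges(c(1001, 2001, 3001, 4001),
                                        c(1400, 2400, 3400, 4400))),
        INNER = GRanges("chr1", IRanges(c(2001, 3001), c(2400, 3400)))))
    set.seed(42)
    n <- 30
    starts1 <- sample(c(1001, 2001, 3001), n, replace = TRUE) +
        sample(0:300, n, replace = TRUE)
    starts2 <- sample(c(2001, 3001, 4001), n, replace = TRUE) +
        sample(0:300, n, replace = TRUE)
    ps <- makePairSet("chr1", starts1, starts1 + 99, 60,
                      starts2, starts2 + 99, 60)
    sup <- assignToGenes(ps, nested)
    params <- detectionParams(min_tlen = 0, min_supported_exons = 2,
                              min_reads_per_exon = 1)
    cand <- callCandidates(sup, nested, params)
    expect_setequal(sort(cand$gene),
                    bruteCandidates(ps, nested, params))
    ## per-exon counts also agree with direct enumeration
    brute <- rep(0L, 4)
    p <- as.data.frame(pairData(ps))
    g <- exons(nested)[["OUTER"]]
    for (i in seq_len(nrow(p))) {
        e1 <- which(p$m1_start[i] <= end(g) & p$m1_end[i] >= start(g))
        e2 <- which(p$m2_start[i] <= end(g) & p$m2_end[i] >= start(g))
        if (length(e1) && length(e2))
            for (k in c(e1, e2)) brute[k] <- brute[k] + 1L
    }
    expect_equal(sup$OUTER$counts, brute)
})

test_that("candidate calling needs 3+ supported exons on intron-bearing genes", {
    gm <- tinyGenes()
    sup <- list(
        G1 = list(counts = c(4L, 2L, 2L), n_pairs = 4L,
                  bridging = data.frame()),
        G3 = list(counts = c(2L, 2L), n_pairs = 2L,
                  bridging = data.frame()),
        G2 = list(counts = 9L, n_pairs = 9L, bridging = data.frame()))
    cand <- callCandidates(sup, gm, detectionParams(), "s1")
    ## G1: 3 supported exons -> called. G3: only 2 ("more than 2 discrete
    ## exons" excludes 2). G2: single-exon gene never called.
    expect_equal(cand$gene, "G1")
    expect_equal(unname(as.list(cand$supported_exons)[[1]]), 1:3)
    ## an exon below min_reads_per_exon does not count as supported
    sup$G1$counts <- c(4L, 2L, 1L)
    expect_equal(nrow(callCandidates(sup, gm, detectionParams())), 0L)
})

test_that("candidate ordering is by pairs desc then symbol", {
    gm <- GeneModelSet(GRangesList(
        B = GRanges("chr1", IRanges(c(1, 101, 201), c(50, 150, 250))),
        A = GRanges("chr1", IRanges(c(1001, 1101, 1201),
                                    c(1050, 1150, 1250))),
        C = GRanges("chr1", IRanges(c(2001, 2101, 2201),
                                    c(2050, 2150, 2250)))))
    sup <- lapply(setNames(c(5L, 5L, 9L), c("B", "A", "C")), function(k)
        list(counts = c(2L, 2L, 2L), n_pairs = k,
             bridging = data.frame()))
    cand <- callCandidates(sup, gm, detectionParams())
    expect_equal(cand$gene, c("C", "A", "B"))
})

test_that("known-retrocopy annotation flags but never removes", {
    gm <- tinyGenes()
    cand <- fakeCand("s1", c("CBX3", "TDG", "NOVEL"))
    out <- annotateKnown(cand, c("TDG", "CBX3"))
    expect_equal(out$flags, c("known_retrocopy", "known_retrocopy", ""))
    expect_equal(nrow(out), 3L)
    expect_warning(annotateKnown(cand, character(0)), "empty")
    empty <- annotateKnown(cand[0, ], c("TDG"))
    expect_equal(nrow(empty), 0L)
})

test_that("spiked retrocopies are recovered and background stays silent", {
    cfg0 <- simulationConfig(seed = 21, n_genes = 8, exonic_coverage = 40)
    genome <- simulateGenome(cfg0)
    eligible <- names(which(nExons(genome$genes) >= 3))[1]
    two_exon <- names(which(nExons(genome$genes) == 2))[1]
    rf <- tempfile()
    writeRefFlat(genome$genes, rf)

    ## spiked 5-exon-class gene at full clonality -> exactly that gene
    cfg <- simulationConfig(seed = 21, n_genes = 8, exonic_coverage = 40,
                            retrocopy_genes = eligible)
    sam <- tempfile(fileext = ".sam")
    simulateSample(genome, cfg, sam, sample_id = "s1")
    cand <- detectSample(sam, rf, sample_id = "s1")
    expect_equal(cand$gene, eligible)

    ## background-only sample -> no candidates
    sam0 <- tempfile(fileext = ".sam")
    simulateSample(genome, cfg0, sam0, sample_id = "s0")
    expect_equal(nrow(detectSample(sam0, rf, sample_id = "s0")), 0L)

    ## spiked 2-exon gene fails the 3-exon rule
    if (!is.na(two_exon)) {
        cfg2 <- simulationConfig(seed = 22, n_genes = 8,
                                 exonic_coverage = 40,
                                 retrocopy_genes = two_exon)
        sam2 <- tempfile(fileext = ".sam")
        simulateSample(genome, cfg2, sam2, sample_id = "s2")
        expect_equal(nrow(detectSample(sam2, rf, sample_id = "s2")), 0L)
    }
})

test_that("candidate TSV report round-trips", {
    cand <- fakeCand("s1", c("A", "B"), c("chr1", "chr2"))
    path <- tempfile(fileext = ".tsv")
    writeCandidatesTsv(cand, path)
    back <- readCandidatesTsv(path)
    expect_equal(back$gene, cand$gene)
    expect_equal(back$chrom, cand$chrom)
    expect_equal(back$n_pairs, cand$n_pairs)
    expect_equal(as.list(back$supported_exons),
                 as.list(cand$supported_exons))
})
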
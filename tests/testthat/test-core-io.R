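test_that("gene models union isoform exons and derive introns", {
    ## two isoforms of GU: [101,200]+[301,400] and [101,250]+[301,400]
    rf <- tempfile()
    writeLines(c(
        paste("GU", "GU.t1", "chr1", "+", 100, 400, 100, 400, 2,
              "100,300,", "200,400,", sep = "\t"),
        paste("GU", "GU.t2", "chr1", "+", 100, 400, 100, 400, 2,
              "100,300,", "250,400,", sep = "\t"),
        paste("SOLO", "SOLO.t1", "chr1", "+", 1000, 1500, 1000, 1500, 1,
              "1000,", "1500,", sep = "\t")), rf)
    gm <- readGeneModels(rf, "refflat")
    expect_setequal(geneSymbols(gm), c("GU", "SOLO"))
    gu <- exons(gm)[["GU"]]
    expect_equal(start(gu), c(101L, 301L))
    expect_equal(end(gu), c(250L, 400L))
    ## introns are the gaps between consecutive union exons
    expect_equal(start(introns(gm)[["GU"]]), 251L)
    expect_equal(end(introns(gm)[["GU"]]), 300L)
    ## single-exon gene: n - 1 = 0 introns
    expect_equal(length(introns(gm)[["SOLO"]]), 0L)
    expect_equal(unname(nExons(gm)[c("GU", "SOLO")]), c(2L, 1L))
})

test_that("refFlat structural errors are rejected", {
    rf <- tempfile()
    writeLines(paste("BAD", "BAD.t1", "chr1", "+", 100, 400, 100, 400, 2,
                     "100,300,", "200,", sep = "\t"), rf)
    expect_error(readGeneModels(rf, "refflat"), "mismatch")
    writeLines(paste("EMPTY", "E.t1", "chr1", "+", 100, 400, 100, 400, 0,
                     ",", ",", sep = "\t"), rf)
    expect_error(readGeneModels(rf, "refflat"), "zero-exon")
})

test_that("BED12 gene models round-trip exactly", {
    gm <- tinyGenes()
    bed <- tempfile(fileext = ".bed")
    writeBed12(gm, bed)
    back <- readGeneModels(bed, "bed12")
    expect_setequal(geneSymbols(back), geneSymbols(gm))
    for (sym in geneSymbols(gm)) {
        expect_equal(start(exons(back)[[sym]]), start(exons(gm)[[sym]]),
                     info = sym)
        expect_equal(end(exons(back)[[sym]]), end(exons(gm)[[sym]]),
                     info = sym)
    }
    ## BED12 with 3 blocks -> 3 exons, 2 introns
    expect_equal(unname(nExons(back)["G1"]), 3L)
    expect_equal(length(introns(back)[["G1"]]), 2L)
})

test_that("gene model invariants are enforced", {
    expect_error(new("GeneModelSet", exons = GRangesList(
        BADSORT = GRanges("chr1", IRanges(c(500, 100), c(600, 400))))),
        "sorted and disjoint")
    expect_error(new("GeneModelSet", exons = GRangesList(
        G = GRanges("chr1", IRanges(1, 10)),
        G = GRanges("chr1", IRanges(20, 30)))), "unique")
})

test_that("SAM pairs are emitted with recomputed template length", {
    sam <- tempfile(fileext = ".sam")
    pairSam(data.frame(qname = "f1", chrom = "chr1",
                       pos1 = 1051, pos2 = 1551), sam)
    rp <- readSamPairs(sam, sample_id = "s1")
    p <- pairData(rp)
    expect_equal(nrow(p), 1L)
    ## mates span 1051-1150 and 1551-1650: ostensible tlen 600
    expect_equal(p$tlen, 600L)
    expect_equal(p$m1_start, 1051L)
    expect_equal(p$m2_end, 1650L)
    expect_equal(parseLog(rp)$records_read, 2L)
})

test_that("cross-chromosome pairs are dropped, clean input preserved", {
    sam <- tempfile(fileext = ".sam")
    df <- data.frame(qname = paste0("f", 1:10), chrom = "chr1",
                     pos1 = seq(1001, by = 500, length.out = 10),
                     pos2 = seq(1301, by = 500, length.out = 10))
    pairSam(df, sam)
    rp <- readSamPairs(sam)
    expect_equal(length(rp), 10L)  # identity on clean input
    ## add a cross-chromosome pair: excluded from the pair stream
    dfx <- rbind(df, data.frame(qname = "fx", chrom = "chr1",
                                pos1 = 2001, pos2 = 2001))
    dfx$chrom2 <- c(rep("chr1", 10), "chr2")
    pairSam(dfx, sam)
    expect_warning(rp2 <- readSamPairs(sam), "dropped")
    expect_equal(length(rp2), 10L)
    expect_false("fx" %in% pairData(rp2)$fragment_id)
})

test_that("malformed SAM lines fail with the line number", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000",
                 "ok\t99\tchr1\t100\t60\t100M\t=\t400\t400\t*\t*",
                 "broken\t99\tchr1"), sam)
    expect_error(readSamPairs(sam), "line 4")
})

test_that("pair span dominates each mate length", {
    sam <- tempfile(fileext = ".sam")
    pairSam(data.frame(qname = c("a", "b"), chrom = "chr1",
                       pos1 = c(101, 5001), pos2 = c(151, 5001)), sam)
    p <- pairData(readSamPairs(sam))
    expect_true(all(p$tlen >= p$m1_end - p$m1_start + 1L))
    expect_true(all(p$tlen >= p$m2_end - p$m2_start + 1L))
})

test_that("VCF reader keeps biallelic SNVs only, hom included", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
        "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0/1:30",
        "chr1\t200\t.\tCA\tC\t.\tPASS\t.\tGT:DP\t0/1:30",
        "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT:DP\t1/1:25",
        "chr1\t400\t.\tA\tC,G\t.\tPASS\t.\tGT:DP\t1/2:25"), vcf)
    v <- readVcfSnvs(vcf)
    expect_equal(length(v), 2L)  # indel and multi-allelic skipped
    expect_equal(metadata(v)$n_skipped, 2L)
    expect_equal(mcols(v)$ref, c("C", "G"))
    expect_equal(mcols(v)$genotype, c("het", "hom"))
    expect_equal(mcols(v)$depth, c(30L, 25L))
})

test_that("simulator VCFs round-trip through the reader", {
    v <- GRanges("chrS", IRanges(c(50, 20), c(50, 20)),
                 ref = c("C", "G"), alt = c("T", "A"),
                 depth = c(12L, 9L), genotype = c("het", "hom"))
    path <- tempfile(fileext = ".vcf")
    writeVcfFile(v, "sim", path)
    back <- readVcfSnvs(path)
    expect_equal(start(back), c(20L, 50L))  # position-sorted
    expect_equal(mcols(back)$ref, c("G", "C"))
    expect_equal(mcols(back)$genotype, c("hom", "het"))
})
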
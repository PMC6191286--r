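test_that("full-length exact placements are found and mismatches rejected", {
    set.seed(42)
    orfSeq <- randomDnaString(120)
    orf <- Biostrings::DNAStringSet(c(CD95L = orfSeq))

    r1 <- substr(orfSeq, 1, 20)
    aln <- matchReadsToORF(SmallReadSet(r1, counts = 4), orf)
    expect_equal(length(aln), 1L)
    expect_equal(GenomicRanges::start(aln), 1L)
    expect_equal(GenomicRanges::end(aln), 20L)
    expect_equal(aln$count, 4)
    expect_equal(aln$nPlacements, 1L)

    # a single mismatch anywhere kills the placement (100%-identity rule)
    for (pos in c(1, 10, 20)) {
        mm <- r1
        substr(mm, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                        substr(r1, pos, pos))[1]
        expect_equal(length(matchReadsToORF(SmallReadSet(mm), orf)), 0L)
    }
})

test_that("reads below minLen are excluded even when they match", {
    set.seed(43)
    orfSeq <- randomDnaString(100)
    orf <- Biostrings::DNAStringSet(c(orf1 = orfSeq))
    short <- substr(orfSeq, 5, 21)  # 17 nt, perfect match
    expect_equal(length(matchReadsToORF(SmallReadSet(short), orf,
                                        minLen = 19)), 0L)
    expect_equal(length(matchReadsToORF(SmallReadSet(short), orf,
                                        minLen = 15)), 1L)
    expect_error(matchReadsToORF(SmallReadSet("ACGT"),
                                 Biostrings::DNAString("")), "non-empty")
})

test_that("placements agree with a naive all-offsets scan", {
    set.seed(44)
    for (rep in 1:25) {
        orfSeq <- randomDnaString(sample(60:150, 1))
        # mix of genuine substrings (some repeated by construction) and
        # random reads of the same lengths
        reads <- character()
        for (k in 1:4) {
            L <- sample(15:25, 1)
            s <- sample(nchar(orfSeq) - L + 1, 1)
            reads <- c(reads, substr(orfSeq, s, s + L - 1))
            reads <- c(reads, randomDnaString(L))
        }
        reads <- unique(reads)
        aln <- matchReadsToORF(SmallReadSet(reads), orfSeq, minLen = 15)
        for (r in reads) {
            exp <- oracleMatchOffsets(r, orfSeq)
            got <- GenomicRanges::start(aln)[aln$sequence == r]
            expect_equal(sort(got), sort(exp))
            if (length(exp))
                expect_true(all(aln$nPlacements[aln$sequence == r] ==
                                length(exp)))
        }
    }
})

test_that("clustering merges on overlap/abutment and respects gap", {
    gr <- function(starts, ends) GenomicRanges::GRanges(
        "t1", IRanges::IRanges(starts, ends), strand = "+",
        count = rep(1, length(starts)))
    # reads at [0,20) and [10,30) (0-based) -> one region [0,30)
    one <- clusterAlignments(gr(c(1, 11), c(20, 30)), gap = 0)
    expect_equal(length(one), 1L)
    expect_equal(GenomicRanges::start(one), 1L)
    expect_equal(GenomicRanges::end(one), 30L)
    expect_equal(one$nReads, 2L)
    # reads at [0,20) and [25,45) stay apart at gap 0, merge at gap 5
    two <- clusterAlignments(gr(c(1, 26), c(20, 45)), gap = 0)
    expect_equal(length(two), 2L)
    expect_equal(length(clusterAlignments(gr(c(1, 26), c(20, 45)),
                                          gap = 5)), 1L)
    # abutting half-open intervals [0,20) + [20,40) merge at gap 0
    expect_equal(length(clusterAlignments(gr(c(1, 21), c(20, 40)),
                                          gap = 0)), 1L)
})

test_that("clustering equals brute-force transitive closure and is stable", {
    set.seed(45)
    for (rep in 1:30) {
        n <- sample(2:12, 1)
        starts <- sample(1:80, n, replace = TRUE)
        ends <- starts + sample(14:24, n, replace = TRUE)
        gap <- sample(0:6, 1)
        aln <- GenomicRanges::GRanges("t1",
                                      IRanges::IRanges(starts, ends),
                                      strand = "+", count = rep(1, n))
        got <- clusterAlignments(aln, gap = gap)
        exp <- oracleClusterMerge(starts, ends, gap = gap)
        expect_equal(GenomicRanges::start(got), exp$start)
        expect_equal(GenomicRanges::end(got), exp$end)
        expect_equal(sum(got$nReads), n)  # each alignment in one region

        # order independence and idempotence
        perm <- sample(n)
        got2 <- clusterAlignments(aln[perm], gap = gap)
        expect_equal(GenomicRanges::start(got2),
                     GenomicRanges::start(got))
        again <- clusterAlignments(got, gap = gap)
        expect_equal(GenomicRanges::start(again),
                     GenomicRanges::start(got))
        expect_equal(GenomicRanges::end(again), GenomicRanges::end(got))
    }
})

test_that("length distributions weight by counts and break peak ties short", {
    rs <- SmallReadSet(c(strrep("ACGTA", 4), strrep("TACGT", 4)),
                       counts = c(3, 3))
    ld <- lengthDistribution(rs)
    expect_equal(meanLength(ld), 20)
    expect_equal(peakLength(ld), 20L)

    # counts {20: 5, 23: 5} -> peak 20 by the shorter-length tie rule
    rs2 <- SmallReadSet(c(strrep("A", 20), strrep("C", 23)),
                        counts = c(5, 5))
    expect_equal(peakLength(lengthDistribution(rs2)), 20L)
    expect_equal(meanLength(lengthDistribution(rs2)), 21.5)

    # rpm weighting sums to 1e6 and leaves the mean unchanged
    ldr <- lengthDistribution(rs2, weightMode = "rpm")
    expect_equal(sum(lengthHistogram(ldr)), 1e6)
    expect_equal(meanLength(ldr), 21.5)

    expect_error(lengthDistribution(SmallReadSet()), "empty")
})

test_that("fraction comparison reports the Ago-shorter signature", {
    rs <- SmallReadSet(c(strrep("A", 20), strrep("C", 23)),
                       counts = c(5, 5))
    d <- lengthDistribution(rs)
    same <- compareFractions(d, d)
    expect_equal(same$meanDifference, 0)
    expect_equal(same$peakDifference, 0L)
    expect_equal(same$ksStatistic, 0)

    cfg <- simulationConfig(seed = 77, nTranscripts = 3,
                            transcriptLengthRange = c(700, 900),
                            readsPerCluster = 300, mirnaFraction = 0)
    tx <- generateTranscriptome(cfg)
    ago <- lengthDistribution(simulateReads(cfg, tx, "ago")$reads)
    tot <- lengthDistribution(simulateReads(cfg, tx, "total")$reads)
    cmp <- compareFractions(ago, tot)
    expect_lt(cmp$meanDifference, 0)
    expect_gt(cmp$ksStatistic, 0)
})

test_that("the weighted KS statistic equals the brute-force ECDF sup", {
    set.seed(46)
    for (rep in 1:25) {
        la <- sample(15:30, sample(3:8, 1))
        lb <- sample(15:30, sample(3:8, 1))
        wa <- sample(1:20, length(la), replace = TRUE)
        wb <- sample(1:20, length(lb), replace = TRUE)
        da <- lengthDistribution(SmallReadSet(strrep("A", la), counts = wa))
        db <- lengthDistribution(SmallReadSet(strrep("A", lb), counts = wb))
        got <- compareFractions(da, db)$ksStatistic
        expect_equal(got, oracleKS(la, lb, wa, wb))
    }
})
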
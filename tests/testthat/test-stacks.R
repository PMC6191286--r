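test_that("pooling collapses identical reads and conserves counts", {
    a <- SmallReadSet("ACGTACGTACGTACGTACG", counts = 6, sample = "s",
                      replicate = "rep1")
    b <- SmallReadSet(c("ACGTACGTACGTACGTACG", "TTGTACGTACGTACGTACG"),
                      counts = c(6, 4), sample = "s", replicate = "rep2")
    pooled <- poolAndCollapse(list(a, b))
    expect_equal(length(pooled), 2L)
    tot <- totalCounts(pooled)
    expect_equal(unname(tot[as.character(readSequences(pooled)) ==
                            "ACGTACGTACGTACGTACG"]), 12)
    expect_equal(sum(tot), sum(totalCounts(a)) + sum(totalCounts(b)))

    # disjoint sequences keep their original counts
    d <- poolAndCollapse(list(
        SmallReadSet("AAAAAAAAAAAAAAAAAAA", counts = 3),
        SmallReadSet("CCCCCCCCCCCCCCCCCCC", counts = 8)))
    expect_setequal(unname(totalCounts(d)), c(3, 8))
})

test_that("read filters apply the stated inclusive boundaries", {
    seqs <- c(strrep("A", 20), strrep("C", 20),  # counts 12 vs 3
              strrep("G", 14), strrep("T", 15), strrep("A", 50),
              strrep("C", 51),
              paste0("ACGTN", strrep("A", 15)))
    rs <- SmallReadSet(seqs, counts = c(12, 3, 100, 100, 100, 100, 100))
    kept <- filterReads(rs, minCount = 10, minLen = 15, maxLen = 50)
    keptSeqs <- as.character(readSequences(kept))
    expect_true(strrep("A", 20) %in% keptSeqs)   # count 12 >= 10
    expect_false(strrep("C", 20) %in% keptSeqs)  # count 3 < 10
    expect_false(strrep("G", 14) %in% keptSeqs)  # <15 nt removed
    expect_true(strrep("T", 15) %in% keptSeqs)   # 15 nt retained
    expect_true(strrep("A", 50) %in% keptSeqs)   # 50 nt retained
    expect_false(strrep("C", 51) %in% keptSeqs)  # >50 nt removed
    expect_false(any(grepl("N", keptSeqs)))      # N-containing removed
    # boundary: exactly 10 copies is retained
    ten <- filterReads(SmallReadSet(strrep("A", 20), counts = 10))
    expect_equal(length(ten), 1L)
})

test_that("unique mapping keeps exactly single-placement reads", {
    set.seed(50)
    cfg <- simulationConfig(seed = 50, nTranscripts = 2,
                            transcriptLengthRange = c(200, 250))
    tx <- generateTranscriptome(cfg)
    t1 <- as.character(tx)[1]
    uniqueRead <- substr(t1, 10, 29)
    multiRead <- paste0(substr(t1, 1, 10), substr(t1, 1, 10))  # may be absent
    absent <- strrep("ACGT", 5)

    # build a transcript set with a deliberate duplicated region
    dupTx <- c(tx, Biostrings::DNAStringSet(c(dup = paste0(
        substr(t1, 5, 60), randomDnaString(100)))))
    rs <- SmallReadSet(unique(c(uniqueRead, multiRead, absent)))
    um <- uniqueMap(rs, dupTx)
    # uniqueRead occurs in tx01 and in 'dup' -> dropped
    expect_false(uniqueRead %in% um$sequence)
    # against the original set it is kept with its single placement
    um2 <- uniqueMap(SmallReadSet(uniqueRead), tx)
    expect_equal(length(um2), 1L)
    expect_equal(as.character(GenomicRanges::seqnames(um2)), "tx01")
    expect_equal(GenomicRanges::start(um2), 10L)
    expect_false(absent %in% um$sequence)
})

test_that("unique mapping agrees with a naive all-transcript scan", {
    set.seed(51)
    for (rep in 1:20) {
        txSeqs <- c(randomDnaString(80), randomDnaString(90))
        # duplicate a stretch across transcripts to create multi-mappers
        txSeqs[2] <- paste0(substr(txSeqs[1], 11, 40),
                            substr(txSeqs[2], 31, 90))
        tx <- Biostrings::DNAStringSet(txSeqs)
        names(tx) <- c("a", "b")
        reads <- unique(c(
            substr(txSeqs[1], 16, 35),   # inside duplicated stretch
            substr(txSeqs[1], 51, 70),   # unique to a
            substr(txSeqs[2], 41, 60),   # unique to b
            randomDnaString(20)))        # absent
        um <- uniqueMap(SmallReadSet(reads), tx)
        for (r in reads) {
            nPlace <- oracleTotalPlacements(r, txSeqs)
            expect_equal(r %in% um$sequence, nPlace == 1L)
        }
    }
})

test_that("stack counting keys on distinct 5' starts only", {
    gr <- GenomicRanges::GRanges(
        c("g1", "g1", "g1", "g1", "g2"),
        IRanges::IRanges(c(7, 7, 7, 30, 5), width = c(20, 21, 22, 20, 20)),
        strand = "+", count = c(10, 11, 12, 13, 14),
        sequence = c("r1", "r2", "r3", "r4", "r5"))
    prof <- countStacks(gr)
    expect_equal(prof$nStacks[prof$transcript == "g1"], 2L)  # starts 7, 30
    expect_equal(prof$nStacks[prof$transcript == "g2"], 1L)
    g1 <- which(prof$transcript == "g1")
    expect_equal(prof$starts[[g1]], c(7L, 30L))
    expect_equal(prof$readsPerStart[[g1]], c(3L, 1L))
    expect_equal(prof$totalCount[g1], 46)
})

test_that("stack counts match an independent set-based pass", {
    set.seed(52)
    for (rep in 1:20) {
        n <- sample(5:30, 1)
        tx <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
        st <- sample(1:40, n, replace = TRUE)
        gr <- GenomicRanges::GRanges(tx, IRanges::IRanges(st, width = 20),
                                     strand = "+", count = rep(1, n))
        prof <- countStacks(gr)
        exp <- oracleStackCounts(tx, st)
        expect_equal(prof$nStacks[match(names(exp), prof$transcript)],
                     unname(exp))
        expect_true(all(prof$nStacks <= tabulate(factor(tx))[
            match(prof$transcript, levels(factor(tx)))]))
    }
})

test_that("stack ranking is deterministic under ties", {
    prof <- S4Vectors::DataFrame(
        transcript = c("g1", "g2", "g3", "g4"),
        nStacks = c(5L, 3L, 5L, 3L),
        totalCount = c(100, 80, 200, 80))
    top <- rankByStacks(prof, topN = 3)
    # g3 beats g1 on totalCount; g2 beats g4 lexicographically
    expect_equal(top$transcript, c("g3", "g1", "g2"))
    expect_equal(rankByStacks(prof, topN = 10)$transcript,
                 c("g3", "g1", "g2", "g4"))
})

test_that("RPKM filtering follows the formula and threshold inclusively", {
    tab <- data.frame(gene_id = c("g1", "g2"),
                      length_nt = c(1000, 2000), count = c(10, 10))
    kept <- rpkmFilter(tab, librarySize = 1e6, minRpkm = 10)
    expect_equal(kept$gene_id, "g1")     # RPKM 10.0 retained at threshold
    expect_equal(kept$rpkm, 10)          # 10 / 1 / 1
    # doubling the library halves every RPKM
    none <- rpkmFilter(tab, librarySize = 2e6, minRpkm = 10)
    expect_equal(nrow(none), 0L)
    all2 <- rpkmFilter(tab, librarySize = 2e6, minRpkm = 0)
    expect_equal(all2$rpkm, c(5, 2.5))
    expect_error(rpkmFilter(data.frame(gene_id = "g", length_nt = 0,
                                       count = 1)), "zero-length")
})

test_that("recovered stacks equal the planted distinct-start counts", {
    cfg <- toyConfig(seed = 63)
    tx <- generateTranscriptome(cfg)
    sim <- simulateReads(cfg, tx, "ago")
    pipeline <- countStacks(uniqueMap(filterReads(
        poolAndCollapse(sim$reads)), tx))
    planted <- vapply(sim$truth$stackStarts, length, integer(1))
    planted <- planted[planted > 0]
    expect_equal(pipeline$nStacks[match(names(planted),
                                        pipeline$transcript)],
                 unname(planted))
    # and the stack positions themselves agree
    for (t in names(planted)) {
        expect_equal(pipeline$starts[[which(pipeline$transcript == t)]],
                     sim$truth$stackStarts[[t]])
    }
})
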
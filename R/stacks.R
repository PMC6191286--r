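#' Pool replicates and collapse identical reads
#'
#' Pools one or more read sets into a single sample and collapses identical
#' sequences, summing copy numbers across replicates and sets. Total copy
#' number is conserved.
#'
#' @param x a \code{SmallReadSet} or a list of them (e.g. one per
#'   replicate file).
#' @param sample sample label of the pooled set.
#' @return a \code{SmallReadSet} with unique sequences and a single count
#'   column \code{"pooled"}.
#' @export
poolAndCollapse <- function(x, sample = NULL) {
    if (is(x, "SmallReadSet")) x <- list(x)
    stopifnot(length(x) >= 1L,
              all(vapply(x, is, logical(1), "SmallReadSet")))
    if (is.null(sample))
        sample <- paste(unique(vapply(x, sampleId, character(1))),
                        collapse = "+")
    seqs <- unlist(lapply(x, function(s) as.character(readSequences(s))))
    tot <- unlist(lapply(x, totalCounts))
    if (length(seqs) == 0L)
        return(SmallReadSet(character(), numeric(0), sample = sample,
                            replicate = "pooled"))
    agg <- tapply(tot, seqs, sum)
    SmallReadSet(names(agg), as.numeric(agg), sample = sample,
                 replicate = "pooled")
}

#' Filter collapsed reads on abundance, length and ambiguity
#'
#' Retains reads whose summed copy number is at least \code{minCount}
#' (default 10), whose length lies in \code{[minLen, maxLen]} nt (defaults
#' 15 and 50; both bounds inclusive) and that contain no N. These are the
#' standard pre-filters applied before unique mapping and stack counting.
#'
#' @param x a collapsed \code{SmallReadSet}.
#' @param minCount minimum total copies (inclusive).
#' @param minLen,maxLen inclusive length bounds in nt.
#' @return the filtered \code{SmallReadSet} (a subset of the input).
#' @export
filterReads <- function(x, minCount = 10, minLen = 15L, maxLen = 50L) {
    stopifnot(is(x, "SmallReadSet"))
    if (length(x) == 0L) return(x)
    seqs <- as.character(readSequences(x))
    lens <- nchar(seqs)
    keep <- totalCounts(x) >= minCount & lens >= minLen & lens <= maxLen &
        !grepl("N", seqs, fixed = TRUE)
    x[keep]
}

#' Uniquely map reads across a transcript set
#'
#' A read is retained only if it has exactly one full-length, 100\%-identity,
#' sense-strand placement across the whole transcript set; that single
#' placement is reported. Reads with zero or multiple placements (on one
#' transcript or across several) are dropped.
#'
#' @param reads a \code{SmallReadSet} (typically collapsed and filtered).
#' @param transcripts a named \code{DNAStringSet} of transcripts.
#' @return a \code{GRanges} with one range per retained read (metadata
#'   columns \code{sequence}, \code{count}, \code{nPlacements} = 1), sorted
#'   by transcript and position.
#' @export
uniqueMap <- function(reads, transcripts) {
    stopifnot(is(reads, "SmallReadSet"))
    if (!is(transcripts, "DNAStringSet") || length(transcripts) == 0L)
        stop("transcripts must be a non-empty DNAStringSet", call. = FALSE)
    if (is.null(names(transcripts)))
        stop("transcripts must be named", call. = FALSE)
    seqs <- as.character(readSequences(reads))
    cnts <- totalCounts(reads)
    recs <- lapply(seq_along(seqs), function(i) {
        m <- Biostrings::vmatchPattern(seqs[i], transcripts)
        n <- S4Vectors::elementNROWS(m)
        if (sum(n) != 1L) return(NULL)
        tx <- which(n == 1L)
        data.frame(tx = names(transcripts)[tx],
                   start = BiocGenerics::start(m[[tx]]),
                   width = nchar(seqs[i]), read = i)
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            sequence = character(), count = numeric(),
            nPlacements = integer())
        return(gr)
    }
    gr <- GenomicRanges::GRanges(
        seqnames = factor(recs$tx, levels = names(transcripts)),
        ranges = IRanges::IRanges(recs$start, width = recs$width),
        strand = "+",
        sequence = seqs[recs$read],
        count = cnts[recs$read],
        nPlacements = 1L)
    BiocGenerics::sort(gr)
}

#' Count stacks (unique read 5' start positions) per transcript
#'
#' A "stack" is the set of reads sharing one 5' start position on a
#' transcript; the per-transcript number of distinct start positions is the
#' stack count, the signature of an mRNA being processed into RISC-loaded
#' fragments. Reads of different lengths sharing a start belong to one
#' stack.
#'
#' @param alignments a \code{GRanges} of uniquely mapped reads (from
#'   [uniqueMap()]).
#' @return a \code{DataFrame} with one row per transcript that has at least
#'   one stack: \code{transcript}, \code{nStacks}, \code{totalCount}, and
#'   list-columns \code{starts} (1-based stack positions),
#'   \code{readsPerStart} and \code{countPerStart}.
#' @export
countStacks <- function(alignments) {
    stopifnot(is(alignments, "GRanges"))
    if (length(alignments) == 0L)
        return(S4Vectors::DataFrame(
            transcript = character(), nStacks = integer(),
            totalCount = numeric(), starts = IRanges::IntegerList(),
            readsPerStart = IRanges::IntegerList(),
            countPerStart = IRanges::NumericList()))
    tx <- as.character(GenomicRanges::seqnames(alignments))
    st <- GenomicRanges::start(alignments)
    cnt <- S4Vectors::mcols(alignments)$count
    if (is.null(cnt)) cnt <- rep(1, length(alignments))
    txs <- unique(tx)
    starts <- lapply(txs, function(t) sort(unique(st[tx == t])))
    readsPerStart <- lapply(seq_along(txs), function(i) {
        vapply(starts[[i]],
               function(p) sum(tx == txs[i] & st == p), integer(1))
    })
    countPerStart <- lapply(seq_along(txs), function(i) {
        vapply(starts[[i]],
               function(p) sum(cnt[tx == txs[i] & st == p]), numeric(1))
    })
    out <- S4Vectors::DataFrame(
        transcript = txs,
        nStacks = vapply(starts, length, integer(1)),
        totalCount = vapply(countPerStart, sum, numeric(1)),
        starts = IRanges::IntegerList(starts),
        readsPerStart = IRanges::IntegerList(readsPerStart),
        countPerStart = IRanges::NumericList(countPerStart))
    out[order(out$transcript), , drop = FALSE]
}

#' Rank transcripts by stack count
#'
#' Orders transcripts by descending stack count; ties are broken by
#' descending total copy number, then by transcript ID, so the ranking is
#' deterministic.
#'
#' @param profiles the \code{DataFrame} returned by [countStacks()].
#' @param topN number of top transcripts to return (default 10); if larger
#'   than the table, the full ranking is returned.
#' @return the reordered (and truncated) \code{DataFrame}.
#' @export
rankByStacks <- function(profiles, topN = 10L) {
    if (topN < 1L) stop("topN must be >= 1", call. = FALSE)
    o <- order(-profiles$nStacks, -profiles$totalCount, profiles$transcript)
    profiles[o[seq_len(min(topN, nrow(profiles)))], , drop = FALSE]
}

#' Filter genes by expression level (RPKM)
#'
#' Computes reads per kilobase of transcript per million mapped reads,
#' \code{RPKM = count / (length_nt/1000) / (librarySize/1e6)}, and keeps
#' genes at or above \code{minRpkm} (default 10, inclusive).
#'
#' @param countTable data.frame with columns \code{gene_id},
#'   \code{length_nt}, \code{count} (see [readGeneCounts()]).
#' @param librarySize total mapped reads in the library; defaults to
#'   \code{sum(countTable$count)}.
#' @param minRpkm inclusive RPKM threshold.
#' @return the retained rows with an added \code{rpkm} column.
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g2"), length_nt = c(1000, 2000),
#'                   count = c(10, 10))
#' rpkmFilter(tab, librarySize = 1e6)  # g1 at RPKM 10 retained, g2 dropped
#' @export
rpkmFilter <- function(countTable, librarySize = NULL, minRpkm = 10) {
    need <- c("gene_id", "length_nt", "count")
    if (!all(need %in% names(countTable)))
        stop("countTable must have columns gene_id, length_nt, count",
             call. = FALSE)
    if (any(countTable$length_nt <= 0))
        stop("zero-length transcript in count table", call. = FALSE)
    if (is.null(librarySize)) librarySize <- sum(countTable$count)
    if (librarySize <= 0) stop("librarySize must be > 0", call. = FALSE)
    rpkm <- countTable$count / (countTable$length_nt / 1000) /
        (librarySize / 1e6)
    out <- countTable
    out$rpkm <- rpkm
    out[out$rpkm >= minRpkm, , drop = FALSE]
}
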
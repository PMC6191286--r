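#' Match small-RNA reads to an ORF by full-length exact identity
#'
#' A read is placed on the target only where its entire sequence matches the
#' sense strand with 100\% identity; every placement is reported. Reads
#' shorter than \code{minLen} or containing N are excluded before matching.
#' The default \code{minLen} of 19 nt reproduces the effect of an e-value
#' cut-off in a BLAST-style search, which only discards short perfect
#' matches.
#'
#' @param reads a \code{SmallReadSet}.
#' @param orf a single target sequence: \code{DNAString}, length-1
#'   \code{DNAStringSet}, or character scalar.
#' @param minLen minimum read length in nt (default 19).
#' @return a \code{GRanges} on the ORF (1-based closed coordinates, strand
#'   \code{"+"}), one range per (read, placement), sorted by position, with
#'   metadata columns \code{sequence}, \code{count} (total copies) and
#'   \code{nPlacements} (number of placements of that read on the target).
#' @examples
#' orf <- Biostrings::DNAStringSet(c(CD95L = paste(rep("ACGTG", 20),
#'                                                 collapse = "")))
#' rs <- SmallReadSet(substr(as.character(orf), 1, 20), counts = 5)
#' matchReadsToORF(rs, orf)
#' @export
matchReadsToORF <- function(reads, orf, minLen = 19L) {
    stopifnot(is(reads, "SmallReadSet"))
    if (minLen < 1L) stop("minLen must be >= 1", call. = FALSE)
    orfId <- "ORF"
    if (is(orf, "DNAStringSet") || is.character(orf)) {
        if (length(orf) != 1L)
            stop("orf must be a single sequence", call. = FALSE)
        if (!is.null(names(orf))) orfId <- names(orf)[1L]
        orf <- Biostrings::DNAString(as.character(orf))
    } else if (!is(orf, "DNAString")) {
        stop("orf must be a DNAString, DNAStringSet or character",
             call. = FALSE)
    }
    if (length(orf) == 0L) stop("orf must be non-empty", call. = FALSE)

    seqs <- as.character(readSequences(reads))
    keep <- which(nchar(seqs) >= minLen & !grepl("N", seqs, fixed = TRUE))
    cnts <- totalCounts(reads)
    hits <- lapply(keep, function(i) {
        m <- Biostrings::matchPattern(seqs[i], orf)
        if (length(m) == 0L) return(NULL)
        data.frame(start = BiocGenerics::start(m),
                   width = nchar(seqs[i]), read = i)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            sequence = character(), count = numeric(),
            nPlacements = integer())
        return(gr)
    }
    nPlace <- table(hits$read)
    gr <- GenomicRanges::GRanges(
        seqnames = orfId,
        ranges = IRanges::IRanges(hits$start, width = hits$width),
        strand = "+",
        sequence = seqs[hits$read],
        count = cnts[hits$read],
        nPlacements = as.integer(nPlace[as.character(hits$read)]))
    BiocGenerics::sort(gr)
}

#' Merge overlapping read placements into cluster regions
#'
#' Placements whose pairwise gap is at most \code{gap} nucleotides are merged
#' transitively into one region. With the default \code{gap = 0}, overlapping
#' or abutting placements merge; the result is independent of input order.
#'
#' @param alignments a \code{GRanges} of read placements (e.g. from
#'   [matchReadsToORF()] or [uniqueMap()]).
#' @param gap maximum separation (nt) merged across; \code{gap = 0} merges
#'   on overlap or abutment only.
#' @return a \code{GRanges} of disjoint regions sorted by position with
#'   metadata columns \code{nReads} (alignments in the region) and
#'   \code{totalCount} (their summed copy numbers; 0s if the input carries
#'   no \code{count} column).
#' @export
clusterAlignments <- function(alignments, gap = 0L) {
    stopifnot(is(alignments, "GRanges"))
    if (gap < 0L) stop("gap must be >= 0", call. = FALSE)
    regions <- GenomicRanges::reduce(GenomicRanges::granges(alignments),
                                     min.gapwidth = gap + 1L)
    regions <- BiocGenerics::sort(regions)
    ov <- GenomicRanges::findOverlaps(alignments, regions)
    nReads <- tabulate(S4Vectors::subjectHits(ov), nbins = length(regions))
    cnt <- S4Vectors::mcols(alignments)$count
    if (is.null(cnt)) cnt <- rep(0, length(alignments))
    totalCount <- vapply(seq_along(regions), function(j) {
        sum(cnt[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]])
    }, numeric(1))
    S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
        nReads = as.integer(nReads), totalCount = totalCount)
    regions
}

#' Weighted read-length distribution
#'
#' Builds a histogram of read lengths weighted either by raw copy counts or
#' by reads per million (RPM). The mean is weight-averaged; the peak is the
#' modal length, with ties broken toward the shorter length so reporting is
#' deterministic.
#'
#' @param x a \code{SmallReadSet}, or a \code{GRanges} of placements whose
#'   widths are the read lengths (metadata column \code{count} used as
#'   weight when present).
#' @param weightMode \code{"raw_count"} or \code{"rpm"}.
#' @return a \code{LengthDistribution}.
#' @export
lengthDistribution <- function(x, weightMode = c("raw_count", "rpm")) {
    weightMode <- match.arg(weightMode)
    if (is(x, "SmallReadSet")) {
        lens <- BiocGenerics::width(readSequences(x))
        w <- totalCounts(x)
    } else if (is(x, "GRanges")) {
        lens <- GenomicRanges::width(x)
        w <- S4Vectors::mcols(x)$count
        if (is.null(w)) w <- rep(1, length(x))
    } else {
        stop("x must be a SmallReadSet or GRanges", call. = FALSE)
    }
    if (length(lens) == 0L || sum(w) <= 0)
        stop("cannot compute a length distribution from empty input",
             call. = FALSE)
    if (weightMode == "rpm") w <- w * 1e6 / sum(w)
    h <- tapply(w, lens, sum)
    hist <- as.numeric(h)
    names(hist) <- names(h)
    hist <- hist[order(as.integer(names(hist)))]
    lengthsInt <- as.integer(names(hist))
    meanL <- sum(lengthsInt * hist) / sum(hist)
    peak <- lengthsInt[which.max(hist)]  # which.max takes first = shortest
    new("LengthDistribution", histogram = hist, meanLength = meanL,
        peakLength = peak, weightMode = weightMode)
}

#' Compare Ago-bound and total read-length distributions
#'
#' Quantifies the trimming signature of RISC loading: Argonaute-bound
#' fragments run shorter than the total small-RNA pool, so
#' \code{meanDifference} and \code{peakDifference} (Ago minus total) are
#' negative when the effect is present. The KS statistic is the supremum
#' distance between the two weighted empirical length distributions.
#'
#' @param ago,total \code{LengthDistribution} objects for the Ago-bound and
#'   total fractions.
#' @return a list with \code{meanDifference}, \code{peakDifference} and
#'   \code{ksStatistic}.
#' @export
compareFractions <- function(ago, total) {
    stopifnot(is(ago, "LengthDistribution"),
              is(total, "LengthDistribution"))
    lens <- sort(unique(c(as.integer(names(ago@histogram)),
                          as.integer(names(total@histogram)))))
    cdf <- function(d) {
        w <- d@histogram[match(as.character(lens), names(d@histogram))]
        w[is.na(w)] <- 0
        cumsum(w) / sum(w)
    }
    list(meanDifference = ago@meanLength - total@meanLength,
         peakDifference = as.integer(ago@peakLength - total@peakLength),
         ksStatistic = max(abs(cdf(ago) - cdf(total))))
}
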
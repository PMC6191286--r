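#' Extract the 6mer seed of a guide sequence
#'
#' The seed is nucleotides 2-7 of the guide strand (1-based), the minimal
#' determinant of miRNA-like targeting. Input shorter than 7 nt has no
#' defined seed and raises an error.
#'
#' @param x character vector of guide/read sequences (RNA alphabet accepted;
#'   U is converted to T).
#' @return character vector of 6mer seeds (DNA alphabet).
#' @examples
#' extractSeed("TGGAATGTAAAGAAGTATGTA")  # "GGAATG"
#' @export
extractSeed <- function(x) {
    x <- toupper(chartr("U", "T", as.character(x)))
    short <- nchar(x) < 7L
    if (any(short))
        stop("seed undefined for sequence of length ", nchar(x)[short][1L],
             " (need >= 7 nt)", call. = FALSE)
    substr(x, 2L, 7L)
}

#' Reads-per-million weights for a read set
#'
#' \code{RPM_i = count_i * 1e6 / sum(counts)}; the weights always sum to
#' 1e6.
#'
#' @param x a \code{SmallReadSet} with positive total copy number.
#' @return numeric vector of RPM weights, one per read record.
#' @export
rpmNormalize <- function(x) {
    stopifnot(is(x, "SmallReadSet"))
    tot <- totalCounts(x)
    if (sum(tot) <= 0)
        stop("total read count must be > 0 for RPM normalization",
             call. = FALSE)
    tot * 1e6 / sum(tot)
}

## bin 1: <20; 2: [20,40); 3: [40,60); 4: [60,80); 5: [80,100]; 6: >100
.SEED_BIN_LABELS <- c("<20%", "20~40%", "40~60%", "60~80%", "80~100%",
                      ">100%")

#' Assign viability values to the six seed-toxicity bins
#'
#' Bins are half-open \code{[lo, hi)} except bin 5, which is closed at 100
#' so that a seed with exactly 100\% viability is reported as "80~100\%",
#' and bin 6, which is everything above 100.
#'
#' @param v numeric vector of percent-viability values.
#' @return integer vector of bin indices in 1..6.
#' @export
seedToxicityBin <- function(v) {
    ifelse(v < 20, 1L,
    ifelse(v < 40, 2L,
    ifelse(v < 60, 3L,
    ifelse(v < 80, 4L,
    ifelse(v <= 100, 5L, 6L)))))
}

#' Aggregate RISC-bound reads into seed-toxicity bins (RPM)
#'
#' Each unique read contributes its RPM weight to the bin containing the
#' viability of its 6mer seed. Reads whose seed is absent from the table
#' accumulate in \code{unmatchedRpm}; binned plus unmatched RPM always
#' equals the total input RPM.
#'
#' @param reads a \code{SmallReadSet}; all reads must be at least 7 nt so
#'   the seed is defined (apply [filterReads()] first).
#' @param table a \code{SeedViabilityTable}.
#' @return a \code{SeedBinSummary}.
#' @export
aggregateSeedToxicity <- function(reads, table) {
    stopifnot(is(reads, "SmallReadSet"), is(table, "SeedViabilityTable"))
    if (length(reads) == 0L)
        stop("cannot aggregate an empty read set", call. = FALSE)
    rpm <- rpmNormalize(reads)
    seeds <- extractSeed(as.character(readSequences(reads)))
    v <- viability(table)[seeds]
    bins <- numeric(6)
    matched <- !is.na(v)
    if (any(matched)) {
        b <- seedToxicityBin(v[matched])
        for (k in 1:6) bins[k] <- sum(rpm[matched][b == k])
    }
    names(bins) <- .SEED_BIN_LABELS
    new("SeedBinSummary", rpmPerBin = bins,
        unmatchedRpm = sum(rpm[!matched]), totalRpm = sum(rpm))
}

#' Sliding-window 6mer toxicity profile of a sequence
#'
#' Enumerates every overlapping 6mer of the sequence (step 1) — the full set
#' of seeds that processing of the sequence into guide RNAs could place into
#' the RISC — and joins each to its viability. A sequence of length L yields
#' L - 5 6mers (e.g. 841 for an 846-nt ORF).
#'
#' @param sequence a character scalar, \code{DNAString}, or length-1
#'   \code{DNAStringSet} of length at least 6 nt.
#' @param table a \code{SeedViabilityTable}; 6mers absent from the table get
#'   \code{NA} viability.
#' @return a \code{DataFrame} with columns \code{position} (1-based start of
#'   the window), \code{kmer} and \code{viability}.
#' @export
sequenceSeedProfile <- function(sequence, table) {
    stopifnot(is(table, "SeedViabilityTable"))
    if (is(sequence, "DNAStringSet")) {
        if (length(sequence) != 1L)
            stop("sequence must be a single sequence", call. = FALSE)
        sequence <- as.character(sequence)
    }
    s <- normalizeDnaInput(as.character(sequence), what = "sequence")
    L <- nchar(s)
    if (L < 6L)
        stop("sequence must be at least 6 nt (got ", L, ")", call. = FALSE)
    pos <- seq_len(L - 5L)
    kmers <- substring(s, pos, pos + 5L)
    S4Vectors::DataFrame(position = pos, kmer = kmers,
                         viability = unname(viability(table)[kmers]))
}

#' Compare the theoretical seed toxicity of two sequences
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the viability value
#' multisets of two [sequenceSeedProfile()] results (asymptotic p-value).
#' Windows without a viability value are dropped.
#'
#' @param profileA,profileB \code{DataFrame}s from [sequenceSeedProfile()].
#' @return a list with \code{ksStatistic}, \code{pValue}, \code{nA},
#'   \code{nB}.
#' @export
compareSequenceToxicity <- function(profileA, profileB) {
    a <- profileA$viability[!is.na(profileA$viability)]
    b <- profileB$viability[!is.na(profileB$viability)]
    if (length(a) == 0L || length(b) == 0L)
        stop("both profiles must carry viability values", call. = FALSE)
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    list(ksStatistic = unname(kt$statistic), pValue = unname(kt$p.value),
         nA = length(a), nB = length(b))
}
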
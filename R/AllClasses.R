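#' @import methods
#' @importFrom Biostrings DNAStringSet matchPattern vmatchPattern writeXStringSet readBStringSet
#' @importFrom S4Vectors DataFrame mcols mcols<- elementNROWS
#' @importFrom IRanges IRanges IntegerList
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand findOverlaps reduce
#' @importFrom BiocGenerics sort
NULL

.READ_ALPHABET <- c("A", "C", "G", "T", "N")

.checkDnaAlphabet <- function(seqs, what = "sequence") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
        sprintf("%s %d contains characters outside {A,C,G,T,N}",
                what, which(bad)[1L])
    } else {
        NULL
    }
}

#' SmallReadSet: collapsed small-RNA reads with per-replicate counts
#'
#' A \code{SmallReadSet} holds deduplicated small-RNA read sequences together
#' with a matrix of occurrence counts, one column per sequencing replicate,
#' and a sample label (e.g. \code{"ago"} for an Argonaute pull-down fraction
#' or \code{"total"} for total small RNAs).
#'
#' @slot sequences \code{DNAStringSet} of read sequences (DNA alphabet; U is
#'   converted to T on input).
#' @slot counts numeric matrix, one row per read, one named column per
#'   replicate; entries are non-negative copy numbers.
#' @slot sample single character sample label.
#'
#' @seealso [readSmallReads()], [poolAndCollapse()], [filterReads()]
#' @export
setClass("SmallReadSet",
    slots = c(sequences = "DNAStringSet", counts = "matrix",
              sample = "character"))

setValidity("SmallReadSet", function(object) {
    msgs <- character()
    if (nrow(object@counts) != length(object@sequences))
        msgs <- c(msgs, "counts must have one row per sequence")
    if (!is.numeric(object@counts))
        msgs <- c(msgs, "counts must be numeric")
    else if (any(!is.finite(object@counts)) || any(object@counts < 0))
        msgs <- c(msgs, "counts must be finite and non-negative")
    if (is.null(colnames(object@counts)) && ncol(object@counts) > 0)
        msgs <- c(msgs, "count columns must be named by replicate")
    if (anyDuplicated(colnames(object@counts)))
        msgs <- c(msgs, "replicate names must be unique")
    if (length(object@sequences) && any(BiocGenerics::width(object@sequences) < 1))
        msgs <- c(msgs, "read sequences must be non-empty")
    if (length(object@sample) != 1L)
        msgs <- c(msgs, "sample must be a single label")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SmallReadSet
#'
#' @param sequences character vector or \code{DNAStringSet} of read sequences.
#'   Lowercase letters are uppercased and U is converted to T.
#' @param counts numeric vector (one replicate) or matrix (reads x replicates)
#'   of copy numbers.
#' @param sample sample label.
#' @param replicate replicate name used when `counts` is a vector.
#' @return A \code{SmallReadSet}.
#' @examples
#' SmallReadSet(c("ACGTACGTACGTACGTACG", "TTTTACGTACGTACGTACG"),
#'              counts = c(12, 3), sample = "ago")
#' @export
SmallReadSet <- function(sequences = character(), counts = NULL,
                         sample = "sample", replicate = "rep1") {
    seqs <- normalizeDnaInput(sequences, what = "read")
    if (is.null(counts))
        counts <- rep(1, length(seqs))
    if (is.null(dim(counts))) {
        counts <- matrix(as.numeric(counts), ncol = 1L,
                         dimnames = list(NULL, replicate))
    } else {
        counts <- as.matrix(counts)
        storage.mode(counts) <- "double"
    }
    new("SmallReadSet", sequences = Biostrings::DNAStringSet(seqs),
        counts = counts, sample = as.character(sample))
}

## uppercases, maps RNA U to DNA T, rejects anything outside {A,C,G,T,N}
normalizeDnaInput <- function(x, what = "sequence") {
    x <- toupper(as.character(x))
    x <- chartr("U", "T", x)
    msg <- .checkDnaAlphabet(x, what = what)
    if (!is.null(msg)) stop(msg, call. = FALSE)
    x
}

#' SeedViabilityTable: 6mer seed to percent-viability map
#'
#' Maps each 6mer seed (the minimal miRNA-like targeting determinant,
#' nucleotides 2-7 of a guide strand) to the average percent cell viability
#' observed when that seed is presented to cells; low viability means a toxic
#' seed. A complete table holds all 4096 DNA 6mers.
#'
#' @slot viability named numeric vector; names are DNA 6mers.
#' @seealso [readViabilityTable()], [generateViabilityTable()],
#'   [aggregateSeedToxicity()]
#' @export
setClass("SeedViabilityTable", slots = c(viability = "numeric"))

setValidity("SeedViabilityTable", function(object) {
    v <- object@viability
    msgs <- character()
    if (length(v) > 4096L)
        msgs <- c(msgs, "at most 4096 seeds allowed")
    if (length(v)) {
        if (is.null(names(v)) || any(nchar(names(v)) != 6L))
            msgs <- c(msgs, "every seed must be a 6mer")
        else if (any(grepl("[^ACGT]", names(v))))
            msgs <- c(msgs, "seeds must be DNA 6mers over {A,C,G,T}")
        if (anyDuplicated(names(v)))
            msgs <- c(msgs, "seeds must be unique")
        if (any(!is.finite(v)))
            msgs <- c(msgs, "viability values must be finite")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SeedViabilityTable
#'
#' @param viability named numeric vector of percent-viability values; names
#'   are 6mers (RNA alphabet accepted, U converted to T).
#' @return A \code{SeedViabilityTable}.
#' @examples
#' SeedViabilityTable(c(ACGTAC = 12.5, GGGGGG = 105))
#' @export
SeedViabilityTable <- function(viability = numeric()) {
    if (length(viability))
        names(viability) <- normalizeDnaInput(names(viability), what = "seed")
    new("SeedViabilityTable", viability = viability)
}

#' LengthDistribution: weighted histogram of read lengths
#'
#' @slot histogram named numeric vector; names are read lengths in
#'   nucleotides, values are weights (raw copy counts or RPM).
#' @slot meanLength weight-averaged mean read length.
#' @slot peakLength modal read length; ties are broken toward the shorter
#'   length.
#' @slot weightMode \code{"raw_count"} or \code{"rpm"}.
#' @seealso [lengthDistribution()], [compareFractions()]
#' @export
setClass("LengthDistribution",
    slots = c(histogram = "numeric", meanLength = "numeric",
              peakLength = "integer", weightMode = "character"))

setValidity("LengthDistribution", function(object) {
    h <- object@histogram
    msgs <- character()
    if (!length(h))
        msgs <- c(msgs, "histogram must be non-empty")
    if (any(h < 0))
        msgs <- c(msgs, "weights must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' SeedBinSummary: RPM aggregated into six seed-toxicity bins
#'
#' The six viability bins are (1) <20\%, (2) 20~40\%, (3) 40~60\%,
#' (4) 60~80\%, (5) 80~100\% (100 inclusive) and (6) >100\%. Reads whose
#' seed is absent from the viability table accumulate in
#' \code{unmatchedRpm}.
#'
#' @slot rpmPerBin numeric vector of length 6.
#' @slot unmatchedRpm RPM of reads whose seed has no table entry.
#' @slot totalRpm total input RPM (bins + unmatched).
#' @seealso [aggregateSeedToxicity()]
#' @export
setClass("SeedBinSummary",
    slots = c(rpmPerBin = "numeric", unmatchedRpm = "numeric",
              totalRpm = "numeric"))

setValidity("SeedBinSummary", function(object) {
    msgs <- character()
    if (length(object@rpmPerBin) != 6L)
        msgs <- c(msgs, "rpmPerBin must have length 6")
    if (any(object@rpmPerBin < 0) || object@unmatchedRpm < 0)
        msgs <- c(msgs, "RPM values must be non-negative")
    if (abs(sum(object@rpmPerBin) + object@unmatchedRpm -
            object@totalRpm) > 1e-6)
        msgs <- c(msgs, "bins plus unmatched must sum to total RPM (1e-6)")
    if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic small-RNA study
#'
#' Describes a simulated experiment: a random transcriptome, clusters of
#' processing sites planted on each transcript, Argonaute-bound and total
#' small-RNA fractions that differ in read length (Ago-bound reads trimmed
#' shorter), a miRNA-like background population of configurable share whose
#' 6mer seeds are drawn from chosen viability bins, and a replicate
#' structure.
#'
#' @slot seed integer master seed; all draws flow from it.
#' @slot nTranscripts number of transcripts to simulate.
#' @slot transcriptLengthRange integer \code{c(min, max)} transcript length
#'   in nt.
#' @slot clustersPerTranscript planted clusters per transcript (used when
#'   \code{plantedClusters} is empty).
#' @slot clusterWidth width in nt of auto-planted clusters.
#' @slot plantedClusters optional list (one element per transcript) of
#'   two-column start/end matrices, 1-based closed coordinates; empty list
#'   means auto-placement.
#' @slot readsPerCluster read events sampled per cluster.
#' @slot agoLengthMean,totalLengthMean mean read length (nt) for the
#'   Ago-bound and total fractions.
#' @slot lengthSd read-length standard deviation (nt).
#' @slot mirnaFraction fraction of read events drawn from the miRNA-like
#'   background pool.
#' @slot nBackgroundReads background read events emitted when
#'   \code{readsPerCluster} is 0.
#' @slot nReplicates number of replicates each read's copies are split over.
#' @slot seedBinMixture six non-negative weights summing to 1: the
#'   probability that a background read's seed falls in each toxicity bin.
#' @slot readCountMean mean total copy number per read event (Poisson).
#' @seealso [simulationConfig()], [simulateReads()]
#' @export
setClass("SimulationConfig",
    slots = c(seed = "integer", nTranscripts = "integer",
              transcriptLengthRange = "integer",
              clustersPerTranscript = "integer", clusterWidth = "integer",
              plantedClusters = "list", readsPerCluster = "integer",
              agoLengthMean = "numeric", totalLengthMean = "numeric",
              lengthSd = "numeric", mirnaFraction = "numeric",
              nBackgroundReads = "integer", nReplicates = "integer",
              seedBinMixture = "numeric", readCountMean = "numeric"))

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    if (length(object@transcriptLengthRange) != 2L ||
        object@transcriptLengthRange[1] > object@transcriptLengthRange[2] ||
        object@transcriptLengthRange[1] < 1L)
        msgs <- c(msgs, "transcriptLengthRange must be c(min, max), min >= 1")
    if (object@mirnaFraction < 0 || object@mirnaFraction > 1)
        msgs <- c(msgs, "mirnaFraction must be in [0, 1]")
    if (length(object@seedBinMixture) != 6L ||
        any(object@seedBinMixture < 0))
        msgs <- c(msgs, "seedBinMixture must be 6 non-negative weights")
    else if (abs(sum(object@seedBinMixture) - 1) > 1e-9)
        msgs <- c(msgs, "seedBinMixture must sum to 1 (tolerance 1e-9)")
    if (object@nReplicates < 1L)
        msgs <- c(msgs, "nReplicates must be >= 1")
    if (object@readsPerCluster < 0L)
        msgs <- c(msgs, "readsPerCluster must be >= 0")
    if (object@lengthSd < 0)
        msgs <- c(msgs, "lengthSd must be >= 0")
    if (length(object@plantedClusters) &&
        length(object@plantedClusters) != object@nTranscripts)
        msgs <- c(msgs, "plantedClusters must have one element per transcript")
    if (length(msgs)) msgs else TRUE
})
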
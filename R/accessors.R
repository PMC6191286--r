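#' @describeIn SmallReadSet-class number of distinct read records
#' @param x a \code{SmallReadSet}
#' @export
setMethod("length", "SmallReadSet", function(x) length(x@sequences))

#' Read sequences of a SmallReadSet
#' @param x a \code{SmallReadSet}
#' @return a \code{DNAStringSet}
#' @export
readSequences <- function(x) x@sequences

#' Per-replicate count matrix of a SmallReadSet
#' @param x a \code{SmallReadSet}
#' @return numeric matrix, reads x replicates
#' @export
readCounts <- function(x) x@counts

#' Total copy number per read (summed over replicates)
#' @param x a \code{SmallReadSet}
#' @return numeric vector
#' @export
totalCounts <- function(x) {
    if (ncol(x@counts) == 0L) numeric(length(x)) else rowSums(x@counts)
}

#' Sample label of a SmallReadSet
#' @param x a \code{SmallReadSet}
#' @return character scalar
#' @export
sampleId <- function(x) x@sample

#' Subset a SmallReadSet by read index
#' @param x a \code{SmallReadSet}
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "SmallReadSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x, sequences = x@sequences[i],
               counts = x@counts[i, , drop = FALSE], sample = x@sample)
})

#' @export
setMethod("show", "SmallReadSet", function(object) {
    cat(sprintf(
        "SmallReadSet: %d unique reads, %d replicate(s), sample '%s'\n",
        length(object), ncol(object@counts), object@sample))
    cat(sprintf("  total copies: %s\n",
                format(sum(totalCounts(object)), big.mark = ",")))
    if (length(object)) {
        w <- BiocGenerics::width(object@sequences)
        cat(sprintf("  read length: %d-%d nt\n", min(w), max(w)))
    }
})

#' Viability values of a SeedViabilityTable
#' @param x a \code{SeedViabilityTable}
#' @return named numeric vector (names are 6mer seeds)
#' @export
viability <- function(x) x@viability

#' @describeIn SeedViabilityTable-class number of seeds in the table
#' @param x a \code{SeedViabilityTable}
#' @export
setMethod("length", "SeedViabilityTable", function(x) length(x@viability))

#' @export
setMethod("show", "SeedViabilityTable", function(object) {
    v <- object@viability
    cat(sprintf("SeedViabilityTable: %d seeds\n", length(v)))
    if (length(v))
        cat(sprintf("  viability range: %.1f%% to %.1f%%\n", min(v), max(v)))
})

#' Histogram of a LengthDistribution
#' @param x a \code{LengthDistribution}
#' @return named numeric vector (names are lengths in nt)
#' @export
lengthHistogram <- function(x) x@histogram

#' Weighted mean read length
#' @param x a \code{LengthDistribution}
#' @export
meanLength <- function(x) x@meanLength

#' Modal read length (ties broken toward shorter)
#' @param x a \code{LengthDistribution}
#' @export
peakLength <- function(x) x@peakLength

#' @export
setMethod("show", "LengthDistribution", function(object) {
    cat(sprintf(
        "LengthDistribution (%s): mean %.2f nt, peak %d nt, %d length bins\n",
        object@weightMode, object@meanLength, object@peakLength,
        length(object@histogram)))
})

#' Per-bin RPM of a SeedBinSummary
#' @param x a \code{SeedBinSummary}
#' @return numeric vector of length 6, named by bin label
#' @export
binRPM <- function(x) x@rpmPerBin

#' RPM of reads with no seed-table entry
#' @param x a \code{SeedBinSummary}
#' @export
unmatchedRPM <- function(x) x@unmatchedRpm

#' @export
setMethod("show", "SeedBinSummary", function(object) {
    cat("SeedBinSummary (RPM per seed-toxicity bin):\n")
    print(round(object@rpmPerBin, 2))
    cat(sprintf("  unmatched: %.2f of %.2f total RPM\n",
                object@unmatchedRpm, object@totalRpm))
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: seed %d, %d transcripts (%d-%d nt)\n",
        object@seed, object@nTranscripts,
        object@transcriptLengthRange[1], object@transcriptLengthRange[2]))
    cat(sprintf(
        "  %d clusters/transcript (%d nt), %d reads/cluster, %d replicate(s)\n",
        object@clustersPerTranscript, object@clusterWidth,
        object@readsPerCluster, object@nReplicates))
    cat(sprintf(
        "  read length: Ago %.1f / total %.1f (sd %.1f) nt; miRNA fraction %.2f\n",
        object@agoLengthMean, object@totalLengthMean, object@lengthSd,
        object@mirnaFraction))
})
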
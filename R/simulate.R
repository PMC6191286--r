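## evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the simulator emulates: Ago-bound
#' reads average 20 nt and total-fraction reads 23 nt (the length shift seen
#' between RISC-bound and total small RNAs), read lengths are clipped to the
#' 15-50 nt window the pipeline filters on, samples come in duplicate, and
#' 34\% of reads are miRNA-like background (the RISC occupancy of a
#' Drosha-knockout regime; a wild-type regime would use ~0.984).
#'
#' @param seed integer master seed.
#' @param nTranscripts,transcriptLengthRange transcriptome size and length
#'   range (nt).
#' @param clustersPerTranscript,clusterWidth planted processing-site
#'   clusters per transcript and their width (nt).
#' @param plantedClusters optional explicit clusters: a list with one
#'   two-column (start, end) matrix per transcript, 1-based closed; empty
#'   list = place automatically.
#' @param readsPerCluster read events sampled per cluster.
#' @param agoLengthMean,totalLengthMean,lengthSd read-length model (nt).
#' @param mirnaFraction fraction of read events from the miRNA-like
#'   background pool.
#' @param nBackgroundReads background events when \code{readsPerCluster}
#'   is 0.
#' @param nReplicates replicates each read's copies are split across.
#' @param seedBinMixture six weights (sum 1): probability that a background
#'   read's seed falls in each toxicity bin.
#' @param readCountMean mean copy number per read event (Poisson).
#' @return a validated \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nTranscripts = 5L,
                             transcriptLengthRange = c(600L, 1000L),
                             clustersPerTranscript = 3L, clusterWidth = 30L,
                             plantedClusters = list(),
                             readsPerCluster = 50L,
                             agoLengthMean = 20, totalLengthMean = 23,
                             lengthSd = 1.5, mirnaFraction = 0.34,
                             nBackgroundReads = 500L, nReplicates = 2L,
                             seedBinMixture = c(0.10, 0.10, 0.15, 0.20,
                                                0.30, 0.15),
                             readCountMean = 30) {
    new("SimulationConfig", seed = as.integer(seed),
        nTranscripts = as.integer(nTranscripts),
        transcriptLengthRange = as.integer(transcriptLengthRange),
        clustersPerTranscript = as.integer(clustersPerTranscript),
        clusterWidth = as.integer(clusterWidth),
        plantedClusters = plantedClusters,
        readsPerCluster = as.integer(readsPerCluster),
        agoLengthMean = agoLengthMean, totalLengthMean = totalLengthMean,
        lengthSd = lengthSd, mirnaFraction = mirnaFraction,
        nBackgroundReads = as.integer(nBackgroundReads),
        nReplicates = as.integer(nReplicates),
        seedBinMixture = seedBinMixture, readCountMean = readCountMean)
}

.MIN_READ_LEN <- 15L
.MAX_READ_LEN <- 50L

.allKmers <- function(s, k) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic transcriptome with globally unique 15-mers
#'
#' Transcript sequences are uniform random DNA, rejection-sampled so that
#' every 15-mer occurs exactly once across (and within) the whole set. Any
#' read of 15 nt or more drawn from a transcript therefore has exactly one
#' sense-strand placement, which makes unique-mapping behaviour exactly
#' predictable.
#'
#' @param config a \code{SimulationConfig}; uses \code{seed},
#'   \code{nTranscripts} and \code{transcriptLengthRange}.
#' @param maxTries rejection-sampling attempts per transcript before giving
#'   up with an error.
#' @return a named \code{DNAStringSet} (\code{tx01}, \code{tx02}, ...),
#'   deterministic given the seed.
#' @export
generateTranscriptome <- function(config, maxTries = 100L) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(config@seed, {
        rng <- config@transcriptLengthRange
        lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L,
                                    config@nTranscripts,
                                    replace = TRUE) - 1L
        seen <- character()
        seqs <- character(config@nTranscripts)
        for (i in seq_len(config@nTranscripts)) {
            ok <- FALSE
            for (try in seq_len(maxTries)) {
                cand <- .randomDna(lens[i])
                km <- .allKmers(cand, 15L)
                if (anyDuplicated(km) || any(km %in% seen)) next
                seqs[i] <- cand
                seen <- c(seen, km)
                ok <- TRUE
                break
            }
            if (!ok)
                stop("could not satisfy 15-mer uniqueness after ", maxTries,
                     " tries for transcript ", i, call. = FALSE)
        }
        out <- Biostrings::DNAStringSet(seqs)
        names(out) <- sprintf("tx%02d", seq_len(config@nTranscripts))
        out
    })
}

#' Generate a synthetic 6mer seed-viability table
#'
#' Emulates a genome-wide seed-toxicity screen: every one of the 4096 DNA
#' 6mers gets a percent-viability value drawn from a mixture over the six
#' toxicity bins (uniform within each bin; bin 6 spans 100-130\%), so all
#' bins from highly toxic (<20\%) to growth-promoting (>100\%) are
#' populated.
#'
#' @param seed integer seed.
#' @param binWeights mixture weights over the six bins (sum 1).
#' @return a \code{SeedViabilityTable} with 4096 entries, deterministic
#'   given the seed.
#' @export
generateViabilityTable <- function(seed = 1L,
                                   binWeights = c(0.10, 0.10, 0.15, 0.20,
                                                  0.30, 0.15)) {
    stopifnot(length(binWeights) == 6L, all(binWeights >= 0),
              abs(sum(binWeights) - 1) < 1e-9)
    withSeed(seed, {
        kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6L)
        lo <- c(0, 20, 40, 60, 80, 100)
        hi <- c(20, 40, 60, 80, 100, 130)
        bin <- sample.int(6L, length(kmers), replace = TRUE,
                          prob = binWeights)
        v <- stats::runif(length(kmers), lo[bin], hi[bin])
        names(v) <- kmers
        SeedViabilityTable(v)
    })
}

## planted clusters per transcript: explicit from config, else evenly
## spaced segments with a random offset; 1-based closed coordinates
.plantClusters <- function(config, transcripts) {
    W <- config@clusterWidth
    k <- config@clustersPerTranscript
    if (length(config@plantedClusters)) {
        cl <- config@plantedClusters
        for (i in seq_along(cl)) {
            m <- cl[[i]]
            if (any(m[, 1] < 1) ||
                any(m[, 2] > BiocGenerics::width(transcripts)[i]))
                stop("planted cluster outside transcript bounds",
                     call. = FALSE)
            if (any(m[, 2] - m[, 1] + 1L < .MIN_READ_LEN))
                stop("planted cluster shorter than the minimum read ",
                     "length (", .MIN_READ_LEN, " nt)", call. = FALSE)
        }
        return(cl)
    }
    if (W < .MIN_READ_LEN)
        stop("clusterWidth shorter than the minimum read length (",
             .MIN_READ_LEN, " nt)", call. = FALSE)
    lapply(BiocGenerics::width(transcripts), function(L) {
        seg <- L %/% k
        if (seg < W + 2L)
            stop("transcripts too short for ", k, " clusters of width ", W,
                 call. = FALSE)
        off <- sample.int(seg - W - 1L, k, replace = TRUE)
        start <- (seq_len(k) - 1L) * seg + off
        cbind(start = start, end = start + W - 1L)
    })
}

## background sequence with its seed (positions 2-7) forced to `seed6`,
## rejection-sampled to be absent from every transcript
.backgroundRead <- function(len, seed6, transcripts, maxTries = 100L) {
    for (try in seq_len(maxTries)) {
        s <- .randomDna(len)
        substr(s, 2L, 7L) <- seed6
        if (sum(Biostrings::vcountPattern(s, transcripts)) == 0L)
            return(s)
    }
    stop("could not draw a background read absent from the transcriptome",
         call. = FALSE)
}

#' Simulate an Ago-bound or total small-RNA read set with ground truth
#'
#' Cluster-derived reads are exact sense-strand substrings of their
#' transcript, with start positions uniform inside the planted cluster and
#' lengths drawn from a discretized Normal (mean 20 nt for the Ago-bound
#' fraction, 23 nt for the total fraction by default) clipped to 15-50 nt
#' and to the cluster width. A \code{mirnaFraction} share of read events is
#' instead drawn from a disjoint miRNA-like pool, absent from the
#' transcriptome by construction, whose 6mer seeds are sampled from the
#' toxicity bins according to \code{seedBinMixture}. Each read event gets a
#' Poisson copy number split multinomially across replicates; identical
#' sequences are collapsed on output.
#'
#' @param config a \code{SimulationConfig}.
#' @param transcripts the \code{DNAStringSet} from
#'   [generateTranscriptome()] (or any named transcript set).
#' @param fraction \code{"ago"} or \code{"total"}.
#' @param table a \code{SeedViabilityTable} used to pick background seeds by
#'   bin and to record true per-bin RPM; defaults to
#'   \code{generateViabilityTable(config@seed)}.
#' @return a list with elements:
#'   \describe{
#'     \item{reads}{a collapsed \code{SmallReadSet} (replicate columns
#'       \code{rep1}, ...).}
#'     \item{truth}{a list: \code{origins} (per read event: sequence,
#'       transcript, start, end, copies, background flag, seed-toxicity
#'       bin), \code{clusters} (\code{GRanges} of planted clusters),
#'       \code{binRPM} (true per-bin RPM over all events),
#'       \code{unmatchedRPM}, \code{stackStarts} (per transcript, the
#'       distinct 5' starts of cluster reads whose collapsed copy number is
#'       at least 10), and \code{nBackground}.}
#'   }
#' @export
simulateReads <- function(config, transcripts,
                          fraction = c("ago", "total"), table = NULL) {
    stopifnot(is(config, "SimulationConfig"),
              is(transcripts, "DNAStringSet"))
    fraction <- match.arg(fraction)
    if (is.null(table)) table <- generateViabilityTable(config@seed)
    if (config@mirnaFraction >= 1 && config@readsPerCluster > 0L)
        stop("mirnaFraction must be < 1 when cluster reads are emitted",
             call. = FALSE)
    lenMean <- if (fraction == "ago") config@agoLengthMean
               else config@totalLengthMean
    subSeed <- config@seed + if (fraction == "ago") 101L else 202L

    withSeed(subSeed, {
        clusters <- .plantClusters(config, transcripts)
        txNames <- names(transcripts)
        txSeq <- as.character(transcripts)

        events <- list()
        for (i in seq_along(txSeq)) {
            cl <- clusters[[i]]
            for (j in seq_len(nrow(cl))) {
                n <- config@readsPerCluster
                if (n == 0L) next
                W <- cl[j, 2] - cl[j, 1] + 1L
                len <- pmin(pmax(round(stats::rnorm(n, lenMean,
                                                    config@lengthSd)),
                                 .MIN_READ_LEN), min(.MAX_READ_LEN, W))
                start <- cl[j, 1] +
                    floor(stats::runif(n) * (W - len + 1L))
                events[[length(events) + 1L]] <- data.frame(
                    sequence = substring(txSeq[i], start, start + len - 1L),
                    transcript = txNames[i], start = start,
                    end = start + len - 1L, background = FALSE,
                    stringsAsFactors = FALSE)
            }
        }
        events <- if (length(events)) do.call(rbind, events) else
            data.frame(sequence = character(), transcript = character(),
                       start = integer(), end = integer(),
                       background = logical())

        nCluster <- nrow(events)
        nBg <- if (config@mirnaFraction == 0) 0L
               else if (nCluster == 0L) config@nBackgroundReads
               else as.integer(round(config@mirnaFraction * nCluster /
                                     (1 - config@mirnaFraction)))
        bgBin <- integer(0)
        if (nBg > 0L) {
            seedsByBin <- split(names(viability(table)),
                                seedToxicityBin(viability(table)))
            need <- which(config@seedBinMixture > 0)
            if (!all(as.character(need) %in% names(seedsByBin)))
                stop("viability table has no seeds in a bin with positive ",
                     "mixture weight", call. = FALSE)
            bgBin <- sample.int(6L, nBg, replace = TRUE,
                                prob = config@seedBinMixture)
            bgLen <- pmin(pmax(round(stats::rnorm(nBg, 22, 1)), 19L), 25L)
            bgSeq <- vapply(seq_len(nBg), function(r) {
                s6 <- sample(seedsByBin[[as.character(bgBin[r])]], 1L)
                .backgroundRead(bgLen[r], s6, transcripts)
            }, character(1))
            events <- rbind(events, data.frame(
                sequence = bgSeq, transcript = NA_character_,
                start = NA_integer_, end = NA_integer_, background = TRUE,
                stringsAsFactors = FALSE))
        }
        if (nrow(events) == 0L)
            stop("configuration emits no reads (readsPerCluster 0 and ",
                 "mirnaFraction 0)", call. = FALSE)

        events$copies <- pmax(1L, stats::rpois(nrow(events),
                                               config@readCountMean))
        ## seed-toxicity bin of every event, via table lookup
        v <- viability(table)[extractSeed(events$sequence)]
        events$bin <- ifelse(is.na(v), NA_integer_, seedToxicityBin(v))

        repCounts <- matrix(
            vapply(events$copies, function(cp) {
                as.numeric(stats::rmultinom(1L, cp,
                                            rep(1, config@nReplicates)))
            }, numeric(config@nReplicates)),
            nrow = nrow(events), ncol = config@nReplicates, byrow = TRUE)
        colnames(repCounts) <- sprintf("rep%d", seq_len(config@nReplicates))

        collapsed <- rowsum(repCounts, events$sequence)
        reads <- SmallReadSet(rownames(collapsed),
                              matrix(collapsed, nrow = nrow(collapsed),
                                     dimnames = list(NULL,
                                                     colnames(collapsed))),
                              sample = fraction)

        ## true per-bin RPM over all events
        rpmEv <- events$copies * 1e6 / sum(events$copies)
        binRPM <- vapply(1:6, function(k) {
            sum(rpmEv[!is.na(events$bin) & events$bin == k])
        }, numeric(1))
        names(binRPM) <- .SEED_BIN_LABELS

        ## distinct 5' starts of cluster reads abundant enough to survive
        ## the >=10-copy filter after collapsing
        seqTotals <- rowsum(events$copies, events$sequence)
        abundant <- rownames(seqTotals)[seqTotals[, 1] >= 10]
        clEv <- events[!events$background &
                       events$sequence %in% abundant, , drop = FALSE]
        stackStarts <- lapply(txNames, function(t) {
            sort(unique(clEv$start[clEv$transcript == t]))
        })
        names(stackStarts) <- txNames

        clGR <- GenomicRanges::GRanges(
            seqnames = rep(txNames, vapply(clusters, nrow, integer(1))),
            ranges = IRanges::IRanges(
                start = unlist(lapply(clusters, function(m) m[, 1])),
                end = unlist(lapply(clusters, function(m) m[, 2]))),
            strand = "+")

        list(reads = reads,
             truth = list(origins = events, clusters = clGR,
                          binRPM = binRPM,
                          unmatchedRPM = sum(rpmEv[is.na(events$bin)]),
                          stackStarts = stackStarts,
                          nBackground = nBg))
    })
}
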
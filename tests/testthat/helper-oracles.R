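## Independent brute-force oracles used to validate the implementation.
## These deliberately avoid Biostrings/GenomicRanges machinery: plain
## character scans and O(n^2) loops.

## all 1-based start positions where `read` matches `orf` exactly
oracleMatchOffsets <- function(read, orf) {
    L <- nchar(read)
    n <- nchar(orf)
    if (L > n) return(integer())
    starts <- integer()
    for (s in seq_len(n - L + 1L)) {
        if (substr(orf, s, s + L - 1L) == read) starts <- c(starts, s)
    }
    starts
}

## total exact placements of `read` across a character vector of transcripts
oracleTotalPlacements <- function(read, txSeqs) {
    sum(vapply(txSeqs, function(t) length(oracleMatchOffsets(read, t)),
               integer(1)))
}

## transitive-closure merge of closed intervals with gap tolerance:
## intervals i,j linked iff start_j <= end_i + gap + 1 (closed coords);
## returns merged intervals sorted by start
oracleClusterMerge <- function(starts, ends, gap = 0L) {
    n <- length(starts)
    if (n == 0L) return(data.frame(start = integer(), end = integer()))
    group <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) {
            for (j in seq_len(n)) {
                if (group[i] != group[j] &&
                    starts[j] <= ends[i] + gap + 1L &&
                    starts[i] <= ends[j] + gap + 1L) {
                    g <- min(group[i], group[j])
                    group[group == group[i] | group == group[j]] <- g
                    changed <- TRUE
                }
            }
        }
        if (!changed) break
    }
    out <- do.call(rbind, lapply(unique(group), function(g) {
        data.frame(start = min(starts[group == g]),
                   end = max(ends[group == g]))
    }))
    out[order(out$start), , drop = FALSE]
}

## distinct 5' start positions per transcript from parallel vectors
oracleStackCounts <- function(tx, starts) {
    vapply(split(starts, tx), function(s) length(unique(s)), integer(1))
}

## per-bin RPM accumulation by an explicit per-read loop
oracleSeedBins <- function(seqs, rpm, viabilityMap) {
    bins <- numeric(6)
    unmatched <- 0
    for (i in seq_along(seqs)) {
        seed <- substr(chartr("U", "T", toupper(seqs[i])), 2, 7)
        v <- viabilityMap[seed]
        if (is.na(v)) {
            unmatched <- unmatched + rpm[i]
        } else {
            b <- if (v < 20) 1 else if (v < 40) 2 else if (v < 60) 3
                 else if (v < 80) 4 else if (v <= 100) 5 else 6
            bins[b] <- bins[b] + rpm[i]
        }
    }
    list(bins = bins, unmatched = unmatched)
}

## two-sample KS statistic as the sup over all observed points of the
## absolute ECDF difference, each ECDF evaluated by explicit counting
oracleKS <- function(a, b, wa = rep(1, length(a)), wb = rep(1, length(b))) {
    pts <- sort(unique(c(a, b)))
    d <- vapply(pts, function(p) {
        abs(sum(wa[a <= p]) / sum(wa) - sum(wb[b <= p]) / sum(wb))
    }, numeric(1))
    max(d)
}

randomDnaString <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
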
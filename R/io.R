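#' Read a transcript (or ORF) set from FASTA
#'
#' Sequences are uppercased and U is converted to T so RNA- and DNA-alphabet
#' inputs interoperate. Transcript IDs are the first whitespace-delimited
#' token of each header and must be unique; empty sequences and characters
#' outside \{A,C,G,T,N\} are rejected with an error naming the record.
#'
#' @param path path to a FASTA file.
#' @return a \code{DNAStringSet}, one entry per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "acgu"), fa)
#' readTranscripts(fa)  # one 4-nt entry, sequence ACGT
#' @export
readTranscripts <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    raw <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(raw))
    seqs <- chartr("U", "T", toupper(as.character(raw)))
    if (any(nchar(ids) == 0))
        stop("FASTA record ", which(nchar(ids) == 0)[1L],
             " has an empty header", call. = FALSE)
    if (anyDuplicated(ids))
        stop("duplicate transcript ID: ", ids[duplicated(ids)][1L],
             call. = FALSE)
    empty <- nchar(seqs) == 0
    if (any(empty))
        stop("record '", ids[empty][1L], "' has an empty sequence",
             call. = FALSE)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("record '", ids[bad][1L],
             "' contains characters outside {A,C,G,T,N}", call. = FALSE)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Read small-RNA reads from FASTA, FASTQ or a collapsed TSV
#'
#' Identical sequences within a replicate are merged with summed counts;
#' FASTQ quality strings are discarded. The collapsed TSV format has columns
#' \code{sequence}, \code{replicate_id}, \code{count} (tab-separated, with
#' header).
#'
#' @param path input file.
#' @param format one of \code{"fasta"}, \code{"fastq"},
#'   \code{"collapsed_tsv"}.
#' @param replicate replicate name assigned to FASTA/FASTQ input (each
#'   sequenced record counts once); ignored for TSV, which carries its own
#'   replicate column.
#' @param sample sample label of the returned set.
#' @return a \code{SmallReadSet}.
#' @export
readSmallReads <- function(path,
                           format = c("fasta", "fastq", "collapsed_tsv"),
                           replicate = "rep1", sample = "sample") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (file.size(path) == 0L && format != "collapsed_tsv")
        return(SmallReadSet(character(), numeric(0), sample = sample,
                            replicate = replicate))
    if (format == "collapsed_tsv") {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE)
        need <- c("sequence", "replicate_id", "count")
        if (!all(need %in% names(tab)))
            stop("collapsed TSV must have columns sequence, replicate_id, ",
                 "count", call. = FALSE)
        if (nrow(tab) == 0L)
            return(SmallReadSet(character(), numeric(0), sample = sample))
        seqs <- normalizeDnaInput(tab$sequence, what = "read")
        reps <- as.character(tab$replicate_id)
        counts <- as.numeric(tab$count)
        if (any(!is.finite(counts)) || any(counts < 0))
            stop("counts must be non-negative numbers", call. = FALSE)
        mat <- tapply(counts, list(seqs, reps), sum, default = 0)
        cmat <- matrix(as.numeric(mat), nrow = nrow(mat),
                       dimnames = list(NULL, colnames(mat)))
        return(SmallReadSet(rownames(mat), cmat, sample = sample))
    }
    raw <- Biostrings::readBStringSet(path, format = format)
    if (length(raw) == 0L)
        return(SmallReadSet(character(), numeric(0), sample = sample,
                            replicate = replicate))
    seqs <- normalizeDnaInput(as.character(raw), what = "read")
    agg <- tapply(rep(1, length(seqs)), seqs, sum)
    SmallReadSet(names(agg), as.numeric(agg), sample = sample,
                 replicate = replicate)
}

#' Write a collapsed-read TSV
#'
#' Long-format TSV with columns \code{sequence}, \code{replicate_id},
#' \code{count}; zero-count cells are omitted. Round-trips losslessly through
#' [readSmallReads()] (up to row order).
#'
#' @param x a \code{SmallReadSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReadsTSV <- function(x, path) {
    stopifnot(is(x, "SmallReadSet"))
    seqs <- as.character(readSequences(x))
    cm <- readCounts(x)
    rows <- do.call(rbind, lapply(seq_len(ncol(cm)), function(j) {
        keep <- cm[, j] > 0
        if (!any(keep)) return(NULL)
        data.frame(sequence = seqs[keep], replicate_id = colnames(cm)[j],
                   count = cm[keep, j], stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
        rows <- data.frame(sequence = character(), replicate_id = character(),
                           count = numeric())
    rows <- rows[order(rows$replicate_id, rows$sequence), , drop = FALSE]
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write alignments or cluster regions as BED6
#'
#' Produces six tab-separated columns: transcript ID, 0-based start,
#' half-open end, name, score, strand (always \code{"+"}, sense strand).
#' For alignments the name is the read sequence and the score its total copy
#' number; for cluster regions the name is \code{cluster_<i>} and the score
#' the summed copy number.
#'
#' @param x a \code{GRanges} as returned by [matchReadsToORF()] (metadata
#'   column \code{sequence} and \code{count}) or [clusterAlignments()]
#'   (metadata columns \code{nReads} and \code{totalCount}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBed <- function(x, path) {
    stopifnot(is(x, "GRanges"))
    if (length(x) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    mc <- S4Vectors::mcols(x)
    if ("sequence" %in% names(mc)) {
        nm <- as.character(mc$sequence)
        sc <- mc$count
    } else if ("totalCount" %in% names(mc)) {
        nm <- sprintf("cluster_%d", seq_along(x))
        sc <- mc$totalCount
    } else {
        nm <- sprintf("region_%d", seq_along(x))
        sc <- rep(0, length(x))
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t+",
                     as.character(GenomicRanges::seqnames(x)),
                     GenomicRanges::start(x) - 1L, GenomicRanges::end(x),
                     nm, format(sc, trim = TRUE, scientific = FALSE))
    writeLines(lines, path)
    invisible(path)
}

#' Read a BED6 file of read placements
#'
#' @param path path to a BED file written by [writeBed()].
#' @return a \code{GRanges} with metadata columns \code{sequence} (the BED
#'   name) and \code{count} (the BED score).
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (file.size(path) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$sequence <- character()
        S4Vectors::mcols(gr)$count <- numeric()
        return(gr)
    }
    gr <- rtracklayer::import(path, format = "BED")
    out <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(gr),
        ranges = IRanges::IRanges(GenomicRanges::start(gr),
                                  GenomicRanges::end(gr)),
        strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(out)$sequence <- as.character(gr$name)
    S4Vectors::mcols(out)$count <- as.numeric(gr$score)
    out
}

#' Read a 6mer seed-viability table from TSV
#'
#' Expects a header with a \code{seed} column and one or more numeric
#' viability columns (percent cell viability). When several viability
#' columns are present (e.g. two cell lines), their per-seed average is
#' used.
#'
#' @param path TSV path.
#' @return a \code{SeedViabilityTable}.
#' @export
readViabilityTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"seed" %in% names(tab))
        stop("viability TSV must have a 'seed' column", call. = FALSE)
    num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "seed"
    if (!any(num))
        stop("viability TSV must have at least one numeric column",
             call. = FALSE)
    vals <- rowMeans(tab[, num, drop = FALSE])
    names(vals) <- tab$seed
    SeedViabilityTable(vals)
}

#' Write a seed-viability table as TSV
#'
#' @param x a \code{SeedViabilityTable}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeViabilityTable <- function(x, path) {
    stopifnot(is(x, "SeedViabilityTable"))
    v <- viability(x)
    utils::write.table(
        data.frame(seed = names(v), viability_percent = unname(v)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene count table for expression filtering
#'
#' TSV with header columns \code{gene_id}, \code{length_nt},
#' \code{count} (uniquely mapped reads from a conventional long RNA-seq
#' library).
#'
#' @param path TSV path.
#' @return a \code{data.frame} with those three columns.
#' @export
readGeneCounts <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "length_nt", "count")
    if (!all(need %in% names(tab)))
        stop("gene count TSV must have columns gene_id, length_nt, count",
             call. = FALSE)
    if (any(tab$length_nt < 1))
        stop("transcript lengths must be >= 1", call. = FALSE)
    if (any(tab$count < 0))
        stop("counts must be non-negative", call. = FALSE)
    tab[, need]
}
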
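## In-code fixtures shared across test files.

writeTempFasta <- function(ids, seqs, ext = ".fa") {
    path <- tempfile(fileext = ext)
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
    path
}

writeTempFastq <- function(seqs, quals = NULL) {
    path <- tempfile(fileext = ".fq")
    if (is.null(quals)) quals <- vapply(nchar(seqs), function(n)
        paste(rep("I", n), collapse = ""), character(1))
    lines <- as.vector(rbind(paste0("@read", seq_along(seqs)), seqs,
                             "+", quals))
    writeLines(lines, path)
    path
}

writeTempReadsTSV <- function(df) {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

## a tiny viability table covering all six bins deterministically
toyViabilityTable <- function() {
    SeedViabilityTable(c(
        AAAAAA = 5, CCCCCC = 25, GGGGGG = 45, TTTTTT = 65,
        ACGTAC = 85, TGCATG = 100, CATCAT = 130, GTAGTA = 12))
}

## small simulation config used by several suites; tiny but realistic
toyConfig <- function(seed = 11L, ...) {
    args <- list(seed = seed, nTranscripts = 3L,
                 transcriptLengthRange = c(400L, 600L),
                 clustersPerTranscript = 2L, readsPerCluster = 30L,
                 mirnaFraction = 0.2)
    args <- utils::modifyList(args, list(...))
    do.call(simulationConfig, args)
}
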
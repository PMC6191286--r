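Package: riscTrace
Title: Analysis of mRNA-Derived Small RNAs Loaded into the RISC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to characterize small RNAs that are processed from
    protein-coding mRNAs and loaded into the RNA-induced silencing complex
    (RISC). Implements strand-specific full-length exact matching of small-RNA
    reads to target open reading frames with merging of overlapping placements
    into cluster regions, comparison of read-length distributions between
    Argonaute-bound and total small-RNA fractions, detection of endogenous
    transcripts processed into RISC-loaded fragments by counting unique read
    5' start positions ("stacks"), RPKM-based expression filtering, and 6mer
    seed toxicity analysis (per-read viability lookup, six-bin RPM
    aggregation, and sliding-window sequence toxicity profiles compared with
    a two-sample Kolmogorov-Smirnov test). A synthetic-data module simulates
    transcriptomes, seed-viability tables, and Argonaute-bound/total read
    sets with planted ground truth so the whole pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, Transcriptomics, Alignment, Software
RoxygenNote: 7.3.3
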
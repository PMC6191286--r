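---
title: "Tracing mRNA-derived small RNAs in the RISC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing mRNA-derived small RNAs in the RISC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riscTrace)
```

# The biological question and the computational model

Overexpressed or endogenous mRNAs can be fragmented into small RNAs that
load into the RNA-induced silencing complex (RISC). Once loaded, a fragment
acts through its 6mer seed (guide nucleotides 2–7) like a miRNA, and
fragments with seeds targeting survival-gene networks are toxic (DISE).
riscTrace implements the sequence-level analyses used to characterize this
phenomenon from small RNA-seq of Argonaute (Ago) pull-down and total
small-RNA fractions. Four analyses are chained, each with explicit,
testable semantics.

## Exact matching and cluster regions

A read is assigned to a target ORF only where its **entire length matches
the sense strand exactly**. This replaces a BLAST search followed by a
100 %-identity filter: for the reads such a filter retains, exact substring
matching is equivalent, and the only effect of the BLAST e-value cut-off is
to discard short perfect matches. We therefore model that cut-off as a
minimum read length, `minLen = 19` nt by default; lowering it to 15 recovers
the short tail. Antisense matching is deliberately absent: the model
considers only fragments in the direction of transcription, and the
simulated data contain none on the antisense strand.

Placements are merged into **cluster regions** by transitive closure:
placements at distance ≤ `gap` join one region, with `gap = 0` (merge on
overlap or abutment) as the default. No published merging rule exists for
this kind of region count, so the gap is a parameter rather than a
constant; region counts on real data should be reported together with the
gap used. Multi-placement reads on the single target are all reported and
flagged via `nPlacements` rather than discarded — within one ORF there is
no ambiguity about the source gene, only about the position.

Internally all intervals are `GRanges`/`IRanges` (1-based, closed), the
single coordinate convention of the Bioconductor stack this package is
built on; BED input/output converts to BED's 0-based half-open convention
at the boundary. Keeping one internal convention and converting only in
the readers/writers is what prevents off-by-one drift.

## Length distributions

Read-length histograms are weighted by copy number (or RPM), the mean is
weight-averaged, and the **peak is the modal length with ties broken toward
the shorter length** so that reported peaks are deterministic. Fractions
are compared by mean difference, peak difference, and the two-sample
Kolmogorov–Smirnov statistic on the weighted empirical distributions —
computed directly as the supremum ECDF distance because the weights are
copy numbers, not unit observations. Empty inputs are an error: a length
distribution of nothing is undefined, not zero.

## Stacks: evidence of processed endogenous mRNAs

The stack pipeline is `poolAndCollapse` → `filterReads` → `uniqueMap` →
`countStacks`:

1. replicates are pooled and identical sequences collapsed (copy number is
   conserved exactly);
2. reads are kept if their summed copy number is **≥ 10**, their length is
   in **[15, 50] nt** (both bounds inclusive) and they contain no N;
3. a read is kept only if it has **exactly one** exact sense-strand
   placement across the whole transcript set (zero or several placements
   drop the read);
4. a **stack** is a distinct read 5' start position on a transcript; reads
   of different lengths sharing a start form one stack. The per-transcript
   stack count is the statistic of interest, and any transcript with at
   least one stack counts as processed.

Two orderings were genuinely open. First, whether uniqueness filtering
precedes or follows the abundance filter: we fix collapse → abundance/
length/N filter → unique mapping → stacks, because filtering first makes
the expensive uniqueness scan run on far fewer reads and neither order
changes which reads satisfy both criteria. Second, whether the ≥10-copy
rule applies per read or per start position: it is applied per read
(a stack may therefore aggregate several reads each with ≥10 copies).

`uniqueMap` deliberately scans a *transcript set*, not a genome. Desk-scale
validation cannot (and should not) reproduce a genome alignment; "aligned
uniquely to the genome" becomes "exactly one placement across the supplied
transcript set". This is a documented divergence: with a transcript set
that omits paralogs or overlapping transcripts, reads unique here could be
multi-mappers genome-wide. Transcript choice (e.g. the isoform with the
longest 3'UTR) is the caller's responsibility when building the set, as is
supplying the matching transcript length to `rpkmFilter`
(RPKM = count / (L/10³) / (library/10⁶), threshold 10, inclusive).

## Seed toxicity

Each read's seed (positions 2–7; reads shorter than 7 nt have no seed and
are an error rather than silently skipped) is looked up in a seed-viability
table mapping each of the 4096 DNA 6mers to a percent cell viability; when
a table carries two cell-line columns their per-seed average is used. Reads
are aggregated into six viability bins. The published bin labels
("20 ~ 40 %", ...) do not state boundary inclusion, so we fix half-open
bins [lo, hi) with two exceptions: bin 5 is [80, 100] **closed** and bin 6
is (100, ∞), so a seed at exactly 100 % viability counts as "80–100 %"
rather than ">100 %". RPM is conserved through binning to within 1e-6, with
seeds missing from the table accumulated in an explicit `unmatchedRpm`
rather than dropped.

A sequence's theoretical toxicity profile enumerates **every overlapping
6mer window** (L − 5 of them; 841 for an 846-nt ORF) — not unique 6mers —
because each window is a potential seed of some processing product, and
repeated windows should weigh as often as they occur. Profiles are compared
with `stats::ks.test` (two-sided, asymptotic p-value; viability values tie
frequently, so an exact small-sample p-value would be invalid anyway).
Binning unique sequences weighted by their summed RPM is arithmetically
identical to binning every duplicate read separately, which is why the
collapsed representation is used throughout.

# The synthetic-data generator

`simulateReads` emulates the features of the real study design that the
pipeline's correctness depends on, with all stochastic draws flowing from
one integer seed:

- **Transcriptome**: uniform random DNA, rejection-sampled so that every
  15-mer is globally unique (across *and within* transcripts). This is
  slightly stronger than requiring transcripts to share no 15-mer, and it
  buys an exact guarantee: every simulated read of ≥ 15 nt has exactly one
  placement, so unique-mapping and stack ground truth are exact, not
  probabilistic.
- **Planted clusters**: by default 3 clusters of 30 nt per transcript,
  placed in equal segments with a random offset, never closer than 2 nt.
  Reads start uniformly inside their cluster and never extend beyond it,
  so at `gap = 0` each planted cluster yields exactly one recovered region
  (with ≥ 15-nt reads in a ≤ 30-nt cluster, any two reads overlap or abut)
  and regions from adjacent clusters never merge.
- **Length shift**: read lengths are `round(Normal(mean, sd))` clipped to
  [15, 50] nt and to the cluster width, with mean 20 nt for the Ago-bound
  fraction and 23 nt for the total fraction (sd 1.5) — the trimming
  signature of RISC loading, in the direction and magnitude of the peak
  shift seen between the fractions (20 → 23 nt).
- **miRNA-like background**: a configurable fraction of read events
  (default 0.34, the RISC occupancy of a miRNA-depleted Drosha-knockout
  regime; a wild-type regime is ≈ 0.984) are ~22-nt sequences
  rejection-sampled to be absent from the transcriptome, so they exercise
  the zero-placement path of every matcher. Their 6mer seeds are drawn
  from the six toxicity bins with probabilities `seedBinMixture`. The seed
  mixture is planted on the background population because those sequences
  are free parameters; cluster-derived reads necessarily inherit whatever
  seeds the transcript sequence encodes, as real mRNA fragments do.
  Mixture-recovery checks therefore run on background-only configurations,
  where per-bin read counts are exactly multinomial and a ±3-standard-error
  band is the right yardstick.
- **Copies and replicates**: each read event receives `max(1, Poisson(30))`
  copies split multinomially across replicates (default 2, matching a
  duplicated library design). A mean of 30 was chosen once so that most
  planted reads clear the ≥10-copy abundance filter while a few fall below
  it, keeping the filter's boundary exercised.

The generator does **not** model sequencing error, quality scores, adapter
contamination, antisense reads, or genome-scale repeat structure. Passing
the recovery tests therefore shows the pipeline's logic is correct under
clean conditions; it does not show robustness to base-calling error (the
100 %-identity rule discards any read with a sequencing error, which on
real data biases against longer reads) or to paralogous gene families.

# Validation strategy and problem sizes

Every non-trivial operation is tested against an independent brute-force
oracle written without the Biostrings/GenomicRanges machinery: an
all-offsets substring scan for matching and unique mapping, an O(n²)
transitive-closure merge for clustering, a set-based pass for stacks, a
per-read loop for bin aggregation, and an exhaustive ECDF evaluation for
the KS statistic — 100 randomized small instances per operation. Recovery
tests run 20 independent simulations (3 transcripts of 400–600 nt, 2
clusters each, 25 reads per cluster) for cluster and stack recovery, a
3000-read background population for mixture recovery, and ~10⁴ reads per
fraction for the length-shift direction; these sizes give the property
being tested essentially no room for false positives while keeping the
whole suite in the low minutes. `scripts/acceptance.R` re-runs the same
measurements from scratch at an arbitrary seed.

# Known limitations

- Exact matching is a faithful model of a 100 %-identity filter, not of
  alignment under sequencing error.
- "Unique" mapping is relative to the supplied transcript set; it is not a
  genome-wide uniqueness guarantee.
- Cluster-region counts depend on the `gap` parameter; there is no
  canonical value, and counts should not be compared across analyses run
  with different gaps.
- The seed-viability table is an external measured resource; the bundled
  generator produces a synthetic stand-in spanning all six bins, suitable
  for validating the machinery but carrying no biological signal.
- The asymptotic KS p-value is approximate for small profiles and in the
  presence of heavy ties; the statistic itself is exact.
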
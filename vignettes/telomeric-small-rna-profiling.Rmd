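---
title: "Profiling telomeric-cluster small RNAs: methods and design notes"
author: "telopirna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling telomeric-cluster small RNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telopirna)
```

## The biological problem

Drosophila telomeres are arrays of the non-LTR retrotransposons HeT-A and
TART, capped by the telomere protection complex (TPC: HOAP, HP1a, Moi, MRN).
When the cap fails, chromosome ends are recognized as double-strand breaks
and covalently fused by non-homologous end joining, which shows up in embryos
as anaphase/telophase chromatin bridges. A 4th-chromosome piRNA cluster
containing fragments of the telomeric transposons — with the elements' sense
strand on the **minus** genomic strand — produces both canonical 23–29 nt
piRNAs and a distinct shorter 19–22 nt minus-strand species. Quantifying
those size classes per genotype, strand-specifically and normalized to
sequencing depth, is the core computation this package implements, together
with the side analyses that accompany it in such studies: efficiency-corrected
ChIP-qPCR percent input, relative telomeric-element copy number against a
single-copy reference gene, and per-embryo bridge-frequency statistics.

## The profiling pipeline

`profile_library()` chains the stages; each is exported on its own.

**Linker trimming** (`trim_linker`). Raw reads still carry the 3' linker. The
insert is everything 5' of the *leftmost* exact occurrence of the linker's
first 6-mer; reads without that 6-mer are discarded and counted. There is no
mismatch tolerance and no full-linker alignment — detection is deliberately a
literal 6-mer match. An `N` never matches (strict reading of a perfect
match). A linker at position 1 yields an empty insert which the length filter
removes; trimming itself has no special case. Because the insert is the
prefix strictly before the first 6-mer, an insert can never contain the
6-mer, so trimming is applied exactly once per raw read and a second pass
would find nothing to cut.

**Length filter** (`length_filter`). Default 18–30 nt, chosen to bracket the
19–29 nt range the size classes use; removed inserts are tallied by length so
the accounting identity *reads in = inserts out + no-linker + length-removed*
holds exactly (`trim_conservation`).

**Exact mapping** (`map_inserts`). Full-length, zero-mismatch matching on
both strands. Internally this is Biostrings' Aho–Corasick dictionary matcher
(`PDict`/`matchPDict`) run per insert length on each chromosome and its
pattern reverse complements; the test suite holds it to exact agreement with
an independent brute-force substring scan. Multi-mappers are retained with
all placements and `n_hits` recorded; a configurable cap (default unlimited)
suppresses reads above it, like an aligner's `-m` option, because repeat-
derived piRNAs need the permissive default while the cap supports
sensitivity analysis. A chromosome blocklist models mapping to a reduced
(e.g. female) genome build. Inserts containing non-ACGT characters can never
match exactly and are counted unmapped.

**ncRNA removal** (`filter_ncrna`). A read whose *any* placement overlaps an
ncRNA/pre-miRNA interval by at least 1 nt is removed entirely —
strand-agnostically and by read, not by placement, because the judgement is
about the sequence's origin, not one location. Intervals are half-open on
disk (BED) and closed in memory (GRanges); an alignment abutting an interval
has zero overlap and is kept.

**Depth and histogram** (`mapped_depth`, `cluster_histogram`). The
normalization denominator is the number of distinct genome-mapping reads
surviving ncRNA removal — reads, never alignments. A read enters the cluster
histogram once if any placement overlaps the cluster span; its strand and
length come from that placement. When placements hit the cluster on both
strands the leftmost placement wins and a warning counter increments —
determinism beats ambiguity. Bins are reads per million depth-countable
reads; the raw bin sum equals the distinct cluster-read count exactly.

**Size classes and fold change** (`size_class_summary`, `fold_change`). The
short class sums lengths 19, 20 and 22 only: the entire 21 nt bin is excluded
because it is dominated by endogenous siRNAs, and the exclusion is structural
(no mixture modelling — the bin is simply left out). The long class is 23–29
inclusive. Fold changes are mutant/wild-type ratios of per-million values;
because both are per-million, any common scaling cancels. A zero wild-type
class flags the ratio undefined rather than dropping the row.

**Cluster attribution** (`cluster_attribution`). Of reads touching any
telomeric-element fragment genome-wide, the fraction that also have a
placement in the cluster. Numerator membership is by read identity: the
element-overlapping placement and the in-cluster placement need not be the
same placement.

**Ping-pong signature** (`ping_pong_signature`). For plus/minus pairs on one
chromosome the 5'-to-5' overlap is `minus_end − plus_start + 1` (1-based
inclusive; the minus read's 5' end is its genomic end). Pair counts over
overlaps 1–30 are computed by position tabulation (equivalent to the O(n²)
pair scan, which the tests enforce on small inputs), and the 10 nt bin gets a
z-score against the mean and SD of the other bins.

## qPCR quantification

**Standard curves** (`fit_efficiency`). Ct is regressed on log10(dilution);
efficiency `E = 10^(−1/slope)`. A perfect doubling assay has slope −3.3219
and E = 2. Fitted efficiencies outside (1, 2.2] are flagged, not rejected.

**Percent input** (`percent_input`). Replicates are averaged on the Ct scale
(geometric averaging of quantities) before exponentiation. The input Ct is
adjusted to represent the full chromatin the IP saw:
`adjusted = Ct_input − log_E(1/input_fraction)`, so
`%input = 100 · input_fraction · E^(Ct_input − Ct_IP)` — linear in the input
fraction, as it must be. Replicate Ct scatter is propagated to the percent
scale by the delta method. Ct ≥ 40 is treated as non-detect and excluded with
a warning. Biological replicates are combined downstream as means of
per-replicate %IP with SD error bars.

**Copy number** (`copy_number`). Relative quantity
`E_t^(−Ct_t)/E_r^(−Ct_r)` per sample against a single-copy reference, then
ratioed to the control sample; with both efficiencies 2 this is exactly the
textbook `2^(−ΔΔCt)`, which the tests check to 1e-12.

## Bridge statistics

Each embryo is one independent observation: ratio = bridged / total A/T
figures, analyzed untransformed. Per genotype the mean and SEM over embryos
are reported; pooling figures across embryos would silently weight embryos by
scoring effort, and a counterexample test keeps that distinction honest.
Genotypes are compared by one-way ANOVA on per-embryo ratios and by
two-tailed t-tests at α = 0.05. Welch's unequal-variance test is the default
because genotype variances differ when bridge probabilities differ; a pooled
Student option exists. P-values are reported raw, matching the convention of
reporting per-pair p-values; a Bonferroni flag is available.

## What the synthetic data emulate — and what they do not

`generate_genome`/`generate_library` build a toy genome whose default
(`demo_genome_spec`) carries a 100 kb "chr4" with a 71 kb cluster — the width
of the real telomeric cluster span — containing six minus-strand
HeT-A/TART-like fragments, plus a 50 kb background chromosome. Libraries are
mixtures of six read classes: minus- and plus-strand 23–29 nt piRNAs, a
sharp 21 nt minus-strand endo-siRNA peak, the 19/20/22 nt minus-strand
species, off-cluster background, and linker-less junk. The wild-type weights
(0.38/0.12/0.08/0.12/0.25/0.05) were fixed once as a plausible ovary-library
composition in which the short species is clearly measurable; they are
configuration, not claims about any real library, since the reanalyzed
datasets' sizes and linker are unpublished. The linker default is an
arbitrary fixed 20-mer; reads are a fixed 40 nt so the 6-mer survives
truncation for the longest insert. `mutant_library_spec` rescales class
weights and rebalances into background so the mapped-depth fraction is
preserved, making the planted depth-normalized fold change exactly the
depletion factor in expectation — the property the recovery tests measure.

Reads carry no sequencing errors by default (`error_rate = 0`): mapping is
exact-match, so errors would silently drop reads, and the rate knob exists
only for robustness exploration. Ground truth (class, origin, strand per
read) is always returned and written; tests compare against it rather than
re-deriving it. The generators are bit-reproducible given (spec, seed).

Not emulated: quality artifacts, adapter errors, ChIP enrichment or chromatin
fragmentation biology, Piwi-IP selectivity, and real repeat structure — every
genome position is an i.i.d. uniform base, so multi-mapping is far rarer than
in a genuine transposon array. Passing recovery tests therefore demonstrate
the pipeline's correctness and calibration on clean mixtures, not robustness
to the multi-mapping ambiguity of real telomeric repeats (the `max_hits` cap
and the per-placement conventions above are where that ambiguity would bite).

One known self-interaction of the simulator: a genome-derived insert can
contain the linker 6-mer by chance (~0.6% of reads at these lengths), in
which case trimming truncates it early. This is realistic — real pipelines
have the same failure mode — and it affects wild-type and mutant libraries
symmetrically, so planted ratios are recovered well inside the 15% band the
tests use.

## Numerical and convention choices

* Coordinates are 1-based closed in memory (GRanges, the natural container
  in R); all BED I/O is 0-based half-open; region strings `"chr:start-end"`
  parse as 1-based inclusive browser notation.
* Strand tie-break in the histogram: leftmost cluster placement, counted.
* Degenerate inputs: depth 0 is an error (nothing to normalize); zero
  wild-type abundance flags, never drops; empty ncRNA track filters nothing;
  an all-junk library conserves reads into the discard ledger.
* Problem sizes in the tests were chosen so every planted effect is measured
  with sampling error well below the asserted band: 2×10^5 reads per library
  for depletion recovery (relative SE ≈ 2% at the deepest depletion),
  100 simulated plates for efficiency bias, 200 simulated datasets for the
  bridge-test power check.

## Limitations

The package is not a general-purpose aligner (no mismatches, no gaps, no
quality awareness), does not discover clusters (the span is an input), does
not model IP enrichment, and treats qPCR from Ct values onward (no
amplification-curve processing). Pairwise cytology p-values are raw by
design; users comparing many genotypes should opt into the correction flag.
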
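---
title: "Length-stratified analysis of CRAC footprints with prioritized multi-mapping rescue"
author: "cracr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-stratified analysis of CRAC footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracr)
```

## The problem

In a CRAC experiment, an RNA-binding complex (here, the RNA exosome via its
catalytic subunit Rrp44/Dis3) is UV-crosslinked to RNA in living cells,
purified under native conditions, and the bound RNA is partially digested
with RNase. Only the region protected by the protein complex survives;
after linker ligation, RT-PCR and sequencing, the read length reports the
protection geometry. For the exosome, three footprint populations are
informative: very short (~10 nt) fragments compatible with a direct-access
route to the exonuclease site, a broad ~20 nt population, and longer
(~39/44 nt) fragments compatible with threading through the central channel
plus the helicases sitting over its entry pore.

The analytical difficulty is the short population. In a yeast-sized genome
(~12.1 Mb, with a transcriptome roughly twice that), a sequence must be
longer than 12 nt to be expected unique, because the number of distinct
12-mers (4^12 ≈ 1.7 × 10^7) only just exceeds the transcriptome size.
8–12 nt reads therefore frequently align to several loci, and naive counting
scatters them into antisense and unannotated ("other") regions that are
barely transcribed.

`cracr` implements the full analysis:

1. **preprocess** — retain only reads in which the 3' sequencing adapter is
   found, trim it, drop inserts shorter than 8 nt and reads dominated by a
   single-nucleotide stretch;
2. **align** — place every insert exhaustively (all exact matches, both
   strands) with a k-mer seed-and-verify index, and stratify mapped reads
   into *short* (8–12 nt) and *long* (≥ 17 nt) populations, leaving
   13–16 nt reads in an *intermediate* class excluded from both;
3. **assign** — the core computation: per-feature RPKM from the long reads,
   a priority order over features (antisense demoted below everything), and
   per-feature counting of each stratum in *default* (random placement) or
   *prioritized* mode;
4. **summarize** — read-length histograms, per-class read fractions and RPKM
   sums with replicate mean ± sd, and per-nucleotide coverage profiles
   normalized per million mapped reads;
5. **synthetic_data** — a ground-truthed simulator producing a genome,
   annotation and adapter-bearing reads with the statistical structure the
   analysis assumes, so every stage can be tested against known read
   provenance.

## The prioritized counting model

For each feature $f$ with length $L_f$ nt and $c_f$ assigned long reads out
of $N$ mapped long reads,

$$\mathrm{RPKM}_f = \frac{c_f \times 10^9}{L_f \, N}.$$

Features are sorted by descending long-read RPKM into a total order, with
two refinements: every antisense feature ranks below every non-antisense
feature (strand-specific transcription data show antisense units are
expressed at very low levels, so short reads landing there are presumed
mis-mapped), and ties break lexicographically by feature id so the order is
reproducible. A multi-mapping read is then counted to the *highest-ranked
feature overlapping any of its placements*. Reads overlapping no feature at
any placement fall back to the pseudo-feature `"other"`.

Two design points were genuinely open:

* **Scope of the priority rule.** Ranking could act after a read has been
  randomly resolved to one placement (choosing among features at that one
  locus), or it could pool the features across *all* candidate placements.
  Only the pooled form can move a read between loci, which is the point of
  the rescue — an ambiguous read should land on the locus most often
  confirmed by unambiguous long reads. Pooled is therefore the default;
  the placement-scoped variant is available via
  `count_prioritized(..., scope = "placement")` for comparison.
* **RPKM normalization total.** Stratum-specific totals are used (long-read
  RPKM over the long-read mapped total, short over short). Output headers
  record this.

Default-mode counting mirrors common overlap counters: each read is resolved
to a single random placement (uniform over its placements, with a per-read
RNG stream derived from the global seed and a hash of the read id, so
results do not depend on record order), and ties among overlapping features
at that placement break lexicographically.

## Read retention rules

* **Adapter.** A qualifying match is a read suffix equal to a prefix of the
  adapter (at least `min_overlap = 4` bases) or a full internal adapter
  occurrence; the leftmost match and everything 3' of it is removed, and
  reads with no qualifying match are discarded. The substitution budget
  scales with the matched length as `min(max_mismatches, m %/% 10)` — exact
  matching below 10 nt, one substitution (default cap) at full adapter
  length. A flat budget at 4-base overlaps would accept ~5% of adapterless
  reads by chance, which both inflates retention and breaks the idempotence
  of trimming; the rate-scaled budget keeps chance matches to ~0.5% of
  reads. Matching is substitution-only (no indels).
* **Length.** Inserts shorter than 8 nt are dropped; 8 nt is also the
  aligner's seed length, so every retained insert is alignable.
* **Complexity.** A read is discarded when its longest contiguous
  homopolymer run exceeds 75% of its length (strictly: a 12-base run in a
  16 nt read, exactly 75%, is kept). "Stretch" is read as contiguity;
  the alternative total-composition reading is available via
  `complexity_policy(method = "composition")` but is not the default, since
  the concern is alignment of runs, and for pure homopolymers the two
  readings coincide.
* **Quality.** The quality filter is a pass-through hook
  (`min_mean_quality`, default disabled): the simulator writes placeholder
  qualities, and real-data users typically quality-filter upstream.

## The aligner

Exact matching only. The index maps every plus-strand 8-mer to its
positions; a query is seeded with its first 8 bases (and the first 8 of its
reverse complement) and each candidate is verified by full-length
comparison, giving *all* loci on both strands. Exact matching keeps the
aligner equivalent to a brute-force scan — the test suite verifies placement
sets against `Biostrings::matchPattern` over whole genomes — which matters
because the counting comparison is only meaningful if the placement sets are
complete. Mismatch-tolerant alignment of real data should be done with a
dedicated aligner and imported through the BED-like placement table
(`read_placements()`); the published analyses this package models also used
an external aligner. Reads with more than 1000 placements are flagged
hyper-repetitive and dropped with a warning.

## What the simulator emulates (and what it does not)

The generator (`simulate_crac_dataset()`) produces, under a single seed,
byte-reproducible FASTA/GFF3/FASTQ plus a truth table recording each read's
source feature, position and protected length. Its defaults are the
package's reference study conditions, chosen once to mirror the structure of
the real data:

* **Genome**: 2 chromosomes × 50 kb of uniform random sequence. At this
  size a 10-mer has roughly a 10% chance of a second chance occurrence —
  the same ambiguity regime that makes real short reads hard to place,
  scaled down from 12.1 Mb so the brute-force oracles stay cheap.
* **Repeats**: `repeat_fraction = 0.1` of the genome is covered by exact
  duplicated blocks of 20–40 nt copied between two distinct features (or a
  feature and intergenic space), so short *and some long* reads genuinely
  multi-map by construction, not only by chance.
* **Features**: 2 pre-rRNA-like units (3–7 kb), 30 mRNAs, 10 CUTs,
  10 SUTs/XUTs, 8 sn/snoRNAs, 10 tRNAs, packed without same-strand overlap;
  30% of features get an antisense twin (identical interval, opposite
  strand, class `"antisense"`), making the antisense demotion rule act on
  concrete records.
* **Abundance**: sampling weights per class, pre-rRNA-dominant
  (0.55 pre-rRNA / 0.20 mRNA / 0.06 CUT / 0.06 SUT-XUT / 0.06 sn-snoRNA /
  0.05 tRNA / 0.02 antisense), the typical shape of exosome-associated RNA
  where rRNA precursors dominate. True in vivo abundances are unknown;
  these weights are user parameters.
* **Lengths**: a mixture of discretized truncated normals with modes
  10 (spread 1, weight 0.35), 20 (spread 3, weight 0.45), 39 and 44
  (spread 1, weight 0.10 each), truncated to 8–50 nt. Only the modes and
  rough shapes are constrained by the footprint phenomenology; the normal
  family is a free choice recorded here. Out-of-range draws are resampled
  rather than clamped, to avoid spurious mass at the truncation bounds;
  lengths exceeding their source feature are likewise redrawn and logged.
* **Adapters**: the standard small-RNA 3' linker is appended with
  probability 0.9, carrying substitution errors at 1% per base; 10% of
  reads lack it and must be discarded by preprocessing. Qualities are the
  constant placeholder `'I'`.

Not modelled: sequencing errors inside the insert, PCR duplicates, 5'
barcodes/UMIs, indels, and expression variation *within* a class. Passing
tests on this data therefore demonstrate the correctness of the counting
logic and the direction of the rescue effect under known truth — not
performance on real libraries, where mismatch-tolerant alignment and
duplicate handling dominate.

## Numerical and degenerate-input choices

* Intervals are 1-based closed internally (the IRanges/GRanges convention);
  GFF3 output is 1-based inclusive and the BED-like placement interchange is
  0-based half-open, as those dialects require.
* Any overlap of at least 1 nt counts a read to a feature
  (`min_overlap_nt = 1`).
* `resolve_random()` seeds one RNG stream per read from
  `(global seed + 31-bit hash of read id) mod (2^31 - 1)` after sorting
  placements canonically, so resolution is reproducible and independent of
  record order.
* Empty strata yield empty (zero-row) count tables; an empty read set is an
  error for `length_histogram()` (a histogram of nothing is undefined).
* Replicate RPKM sums use the sample (n−1) standard deviation; a single
  replicate reports sd 0 with `n_replicates = 1` as the flag.
* Pileups use the placement consistent with the assignment (in prioritized
  mode, the placement inside the winning feature with the smallest start),
  and the per-million denominator is the stratum's mapped total, recorded in
  the output attributes.
* Infeasible simulator configurations (catalogue larger than the genome,
  repeat blocks that cannot be placed disjointly) raise errors naming the
  constraint rather than silently truncating.

## Scale of the shipped checks

The reference conditions run 50,000 reads through the whole pipeline in
under a minute on one core; the oracle-equivalence suite uses twenty smaller
genomes (12–30 kb) so that naive full-genome rescans remain the reference.
Mode-recovery checks draw 10^5 lengths. These sizes were chosen so the
entire suite re-derives every number it asserts.

## Known limitations

* Exact-match alignment: a single sequencing error inside an insert makes
  it unmappable here (import external alignments for real data).
* Flat feature model: no gene/transcript/exon hierarchy, no splicing.
* The priority order is fully automatic (RPKM + antisense demotion); the
  original analyses may have hand-curated parts of their order beyond the
  antisense rule.
* No fractional (EM-style) multi-map assignment: each read is counted once,
  to one feature.
* No assembly of longer fragments from overlapping short reads.
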
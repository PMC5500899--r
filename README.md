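# cracr

Length-stratified analysis of RNase-protected RNA footprints from CRAC/CLIP
crosslinking experiments, with RPKM-prioritized rescue of ambiguously mapping
short reads.

## The problem

CRAC couples in vivo UV crosslinking of a protein–RNA complex to partial
RNase digestion, so the length of each sequenced fragment reports how much
RNA the complex protected — for the RNA exosome, ~10 nt (direct access to the
Rrp44 exonuclease), a broad ~20 nt population, and ~39/44 nt (threading
through the central channel plus associated helicases). The short 8–12 nt
population is the interesting one and the hardest to use: sequences of 12 nt
or less are not expected to be unique in a yeast-sized genome (there are only
4^12 ≈ 1.7 × 10^7 distinct 12-mers), so short reads align to multiple loci
and naive counting scatters them into antisense and unannotated regions.

`cracr` implements the whole analysis for scientists working with
footprint-length data:

* **Retention rules** — 3'-adapter requirement and trimming (substitution
  budget scaled to the matched length), minimum insert length 8 nt, and a
  low-complexity filter (longest homopolymer run > 75% of the read).
* **Exhaustive exact alignment** — a k-mer seed-and-verify index returns
  *all* placements on both strands; reads are stratified into short
  (8–12 nt), intermediate (13–16 nt, excluded downstream) and long
  (≥ 17 nt) populations. External alignments can be imported as a BED-like
  table instead.
* **Prioritized counting** — the core method. Per-feature RPKM
  (count × 10⁹ / (length × total mapped)) is computed from the long-read
  population; features are ranked by descending RPKM with every antisense
  feature demoted below all others; a multi-mapping read is counted to the
  highest-ranked feature overlapping *any* of its placements. The
  conventional alternative (`count_default()`: one random placement,
  lexicographic tie-break) is included for comparison.
* **Summaries** — read-length histograms, per-class read fractions and RPKM
  sums with replicate mean ± sd, per-nucleotide coverage pileups in hits per
  million mapped reads.
* **Ground-truthed simulator** — genome + annotation + adapter-bearing reads
  with a multi-modal footprint-length mixture, skewed class abundances,
  antisense twins and exact repeat blocks, plus a truth table, so
  mis-assignment is measurable.

## Worked example

Simulate the reference conditions (50,000 reads, 2 × 50 kb genome, 10%
duplicated sequence, seed 42) and run the full pipeline:

```r
library(cracr)

sim <- simulate_crac_dataset(n_reads = 50000, seed = 42)
res <- run_crac_pipeline(sim$fastq$sequences, sim$genome, sim$features,
                         seed = 42)

res$tally
#>          input       retained     no_adapter      too_short low_complexity
#>          50000          44166           5819             12              3
res$totals
#>        short intermediate         long
#>        15376         2375        26415
head(res$priority, 5)
#>   rank    feature_id     class  rpkm
#> 1    0  pre_rRNA_002  pre_rRNA 72513
#> 2    1      tRNA_009      tRNA 67529
#> 3    2      tRNA_010      tRNA 58832
#> 4    3      tRNA_002      tRNA 57284
#> 5    4 sn_snoRNA_007 sn_snoRNA 57263
```

About 12% of reads are rejected (mostly simulated adapterless reads), and
the mapped reads split into the two analyzed populations. The priority list
is headed by the most heavily bound features per kilobase — a pre-rRNA unit
and short, densely covered tRNAs/snoRNAs.

Because the simulator records each read's true origin, the rescue effect is
directly measurable:

```r
misassignment_rate(res$counts$short_default$assignments, sim$truth)      # 0.192
misassignment_rate(res$counts$short_prioritized$assignments, sim$truth)  # 0.037

other_antisense_fraction(res$counts$short_default$counts)      # 0.151
other_antisense_fraction(res$counts$short_prioritized$counts)  # 0.016

histogram_modes(length_histogram(res$inserts))
#> [1] 10 20 39 44
```

Prioritized counting cuts the short-read mis-assignment rate from 19% to
under 4%, and the fraction of short reads landing in "other"/antisense
regions — the hallmark of mis-mapping — drops from 15% to under 2%. The
length histogram of retained inserts recovers all four footprint modes.

A command-line front-end over the same functions is installed at
`inst/cli/cracr` (subcommands `simulate`, `preprocess`, `align`, `count`,
`summarize`).

## Documentation

The methods vignette (`vignettes/crac-footprint-analysis.Rmd`) describes the
model, the retention and counting rules, the simulator's design and its
limits, and the numerical choices. Function-level documentation is in the
roxygen comments in `R/`.
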
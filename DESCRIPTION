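Package: cracr
Title: Length-Stratified Analysis of CRAC RNA Footprints with Prioritized
    Multi-Mapping Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing RNase-protected RNA footprints from
    CRAC/CLIP-style crosslinking experiments. Reads are retained by a
    3'-adapter rule, trimmed, filtered for low-complexity homopolymer
    stretches, exhaustively placed on the genome by an exact k-mer
    seed-and-verify aligner, and stratified into short (8-12 nt) and long
    (>= 17 nt) footprint populations. Ambiguously mapping short reads are
    rescued by prioritized counting: features are ranked by RPKM computed
    from the long-read population (antisense features demoted below all
    others) and each multi-mapping read is assigned to the highest-ranked
    overlapping feature. Includes a ground-truthed synthetic-data
    generator (genome, annotation, adapter-bearing footprint reads with a
    multi-modal length mixture and deliberate sequence repetition),
    per-class count/RPKM summaries with replicate statistics, read-length
    histograms, and per-million normalized coverage pileups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
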
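# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use naive loops / Biostrings pattern matching so they
# share no code path with the package implementation they check.

# deterministic 400 nt single-chromosome genome with a sense mRNA (+ antisense
# twin), a CUT, and intergenic space; optionally a 30 nt block duplicated
# between the mRNA and the CUT
tiny_fixture <- function(duplicate_block = FALSE) {
  set.seed(99)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  if (duplicate_block) {
    block <- substr(s, 101, 130)            # inside mRNA_A [51, 200]
    substr(s, 261, 290) <- block            # inside CUT_B  [251, 330]
  }
  genome <- Biostrings::DNAStringSet(s)
  names(genome) <- "chrT"
  features <- GenomicRanges::GRanges(
    seqnames = "chrT",
    ranges = IRanges::IRanges(start = c(51, 51, 251), end = c(200, 200, 330)),
    strand = c("+", "-", "+"),
    feature_id = c("mRNA_A", "antisense_mRNA_A", "CUT_B"),
    class = c("mRNA", "antisense", "CUT"),
    seqlengths = c(chrT = 400L))
  list(genome = genome, features = features, seq = s)
}

# small catalogue that fits comfortably in a 15-30 kb chromosome
small_catalog <- function() {
  feature_catalog(
    classes = list(
      pre_rRNA  = list(n = 1L, len = c(1500L, 2500L)),
      mRNA      = list(n = 8L, len = c(300L, 900L)),
      CUT       = list(n = 4L, len = c(150L, 400L)),
      SUT_XUT   = list(n = 4L, len = c(150L, 400L)),
      sn_snoRNA = list(n = 3L, len = c(80L, 200L)),
      tRNA      = list(n = 4L, len = c(70L, 120L))
    ),
    antisense_fraction = 0.3,
    abundance_weights = c(pre_rRNA = 0.5, mRNA = 0.22, CUT = 0.07,
                          SUT_XUT = 0.07, sn_snoRNA = 0.07, tRNA = 0.05,
                          antisense = 0.02))
}

# oracle aligner: full-genome scan with Biostrings::matchPattern, both strands
oracle_align <- function(inserts, genome) {
  ids <- names(inserts)
  rows <- list()
  for (i in seq_along(inserts)) {
    q <- Biostrings::DNAString(as.character(inserts[[i]]))
    qrc <- Biostrings::reverseComplement(q)
    for (cm in names(genome)) {
      for (st in c("+", "-")) {
        m <- Biostrings::matchPattern(if (st == "+") q else qrc, genome[[cm]])
        if (length(m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = ids[i], chrom = cm,
            start = Biostrings::start(m), end = Biostrings::end(m),
            strand = st)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  out[order(out$read_id, out$chrom, out$start, out$strand), , drop = FALSE]
}

# oracle adapter detector: naive per-read scan for the leftmost 3'-anchored
# adapter match (substitution budget scaling as min(cap, overlap %/% 10))
oracle_trim_pos <- function(r, trim) {
  adapter <- trim$adapter_seq
  alen <- nchar(adapter)
  len <- nchar(r)
  for (i in seq_len(len)) {
    m <- min(alen, len - i + 1L)
    if (m < trim$min_overlap) break
    if (m < alen && (i + m - 1L) < len) next  # not anchored, not full
    a <- strsplit(substr(adapter, 1, m), "")[[1]]
    b <- strsplit(substr(r, i, i + m - 1L), "")[[1]]
    if (sum(a != b) <= min(trim$max_mismatches, m %/% 10L)) return(i)
  }
  NA_integer_
}

oracle_has_adapter <- function(seqs, trim) {
  !is.na(vapply(seqs, oracle_trim_pos, integer(1), trim = trim))
}

# oracle preprocessing: naive re-implementation of the retention rules
# (adapter match, min length, longest-homopolymer rule)
oracle_preprocess <- function(seqs, trim, complexity) {
  out <- character(0)
  for (id in names(seqs)) {
    r <- seqs[[id]]
    pos <- oracle_trim_pos(r, trim)
    if (is.na(pos)) next
    insert <- substr(r, 1, pos - 1L)
    if (nchar(insert) < trim$min_length) next
    ch <- strsplit(insert, "")[[1]]
    if (max(rle(ch)$lengths) / length(ch) >
        complexity$max_homopolymer_fraction) next
    out[id] <- insert
  }
  out
}

# oracle counting: naive same-strand interval overlap + assignment rules
feature_df <- function(features) {
  data.frame(feature_id = S4Vectors::mcols(features)$feature_id,
             class = S4Vectors::mcols(features)$class,
             chrom = as.character(GenomicRanges::seqnames(features)),
             start = IRanges::start(features),
             end = IRanges::end(features),
             strand = as.character(GenomicRanges::strand(features)))
}

oracle_overlaps <- function(chrom, start, end, strand, fdf) {
  hit <- fdf$chrom == chrom & fdf$strand == strand &
    fdf$start <= end & fdf$end >= start
  fdf$feature_id[hit]
}

# brute-force recount of default-mode assignment given resolved placements
oracle_count_default <- function(chosen, fdf) {
  asg <- vapply(seq_len(nrow(chosen)), function(i) {
    f <- oracle_overlaps(chosen$chrom[i], chosen$start[i], chosen$end[i],
                         chosen$strand[i], fdf)
    if (length(f)) sort(f)[1] else "other"
  }, character(1))
  table(asg)
}

# brute-force recount of prioritized (pooled) assignment over all placements
oracle_count_prioritized <- function(records, fdf, priority) {
  ids <- unique(records$read_id)
  asg <- vapply(ids, function(rid) {
    rr <- records[records$read_id == rid, ]
    pool <- unique(unlist(lapply(seq_len(nrow(rr)), function(i) {
      oracle_overlaps(rr$chrom[i], rr$start[i], rr$end[i], rr$strand[i], fdf)
    })))
    if (!length(pool)) return("other")
    priority$feature_id[min(match(pool, priority$feature_id))]
  }, character(1))
  table(asg)
}
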
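#' Build a k-mer index over the genome
#'
#' Indexes every plus-strand k-mer position of every chromosome. Minus-strand
#' hits are found at query time by looking up the reverse complement of the
#' read, so each genomic position carries one index entry.
#'
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosomes.
#' @param k Seed length (default 8, the shortest retainable insert).
#' @return An object of class `kmer_index`: a keyed `data.table`
#'   (`kmer`, `chrom`, `pos` 1-based) plus the chromosome sequences used for
#'   seed extension.
#' @export
build_kmer_index <- function(genome, k = 8L) {
  stopifnot(k >= 4)
  chrom_str <- stats::setNames(as.character(genome), names(genome))
  tabs <- lapply(names(chrom_str), function(nm) {
    L <- nchar(chrom_str[[nm]])
    if (L < k) {
      warning("chromosome ", nm, " shorter than k = ", k, "; skipped")
      return(NULL)
    }
    n <- L - k + 1L
    data.table::data.table(kmer = substring(chrom_str[[nm]], 1:n, k:L),
                           chrom = nm, pos = 1:n)
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  structure(list(k = as.integer(k), table = idx, chrom_str = chrom_str),
            class = "kmer_index")
}

#' Exhaustively place inserts on the genome (exact matching)
#'
#' Seed-and-verify: the first k bases of the insert (and of its reverse
#' complement) are looked up in the index and every candidate is verified by
#' full-length exact comparison. All matching loci on both strands are
#' returned; a match of the reverse complement at plus-strand position `s` is
#' reported as a minus-strand placement over the same interval.
#'
#' @param inserts Named character vector or `DNAStringSet` of inserts (each
#'   at least `k` long).
#' @param index A [build_kmer_index()].
#' @param max_placements Reads with more placements are flagged
#'   hyper-repetitive and dropped from the output with a warning
#'   (default 1000).
#' @return A `data.table` with one row per placement: `read_id`,
#'   `insert_length`, `chrom`, `start` (1-based), `end`, `strand`,
#'   `n_placements`, `stratum`. Unmapped reads have no rows; their ids are in
#'   `attr(, "unmapped")`, hyper-repetitive ids in `attr(, "hyper_repetitive")`.
#' @export
align_reads <- function(inserts, index, max_placements = 1000L) {
  seqs <- toupper(as.character(inserts))
  ids <- names(inserts) %||% sprintf("read_%06d", seq_along(seqs))
  stopifnot(all(nchar(seqs) >= index$k))
  k <- index$k
  rc <- revcomp(seqs)
  q <- data.table::data.table(
    read_id = rep(ids, 2L),
    query = c(seqs, rc),
    strand = rep(c("+", "-"), each = length(seqs)),
    kmer = substr(c(seqs, rc), 1L, k))
  cand <- index$table[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0) {
    hits <- data.table::data.table(read_id = character(),
                                   insert_length = integer(),
                                   chrom = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   n_placements = integer(),
                                   stratum = character())
    attr(hits, "unmapped") <- ids
    attr(hits, "hyper_repetitive") <- character()
    return(hits)
  }
  cand[, len := nchar(query)]
  cand[, end := pos + len - 1L]
  cand <- cand[end <= nchar(index$chrom_str[chrom])]
  # verify seed hits by full-length comparison against the genome
  cand[, genome_seq := substring(index$chrom_str[chrom], pos, end)]
  hits <- cand[genome_seq == query,
               .(read_id, insert_length = len, chrom, start = pos, end, strand)]
  hits[, n_placements := .N, by = read_id]
  hyper <- unique(hits$read_id[hits$n_placements > max_placements])
  if (length(hyper)) {
    warning(length(hyper), " hyper-repetitive read(s) exceeded ",
            max_placements, " placements and were dropped")
    hits <- hits[!read_id %in% hyper]
  }
  hits[, stratum := stratum_of(insert_length)]
  data.table::setorder(hits, read_id, chrom, start, strand)
  attr(hits, "unmapped") <- setdiff(ids, hits$read_id)
  attr(hits, "hyper_repetitive") <- hyper
  hits[]
}

#' Place a single insert
#'
#' @param insert A single sequence.
#' @inheritParams align_reads
#' @return Data table of placements (possibly zero rows).
#' @export
align_read <- function(insert, index, max_placements = 1000L) {
  align_reads(stats::setNames(as.character(insert)[1], "query"), index,
              max_placements)
}

#' Length stratum of mapped reads
#'
#' Mapped reads of 8-12 nt are the "short" population, reads >= 17 nt the
#' "long" population; 13-16 nt reads are "intermediate" and excluded from
#' both downstream counting populations (they remain in length histograms).
#'
#' @param length_nt Integer vector of insert lengths (>= 8; shorter inserts
#'   are removed during preprocessing).
#' @return Character vector: `"short"`, `"intermediate"` or `"long"`.
#' @export
stratum_of <- function(length_nt) {
  stopifnot(all(length_nt >= 8))
  ifelse(length_nt >= 17L, "long",
         ifelse(length_nt <= 12L, "short", "intermediate"))
}

#' Partition alignment records by length stratum
#'
#' @param records Placement table from [align_reads()].
#' @return Named list of data tables: `short`, `intermediate`, `long`.
#'   The union is the full record set; the parts are disjoint.
#' @export
stratify_reads <- function(records) {
  lapply(stats::setNames(c("short", "intermediate", "long"),
                         c("short", "intermediate", "long")),
         function(s) records[records$stratum == s, ])
}

#' Resolve a multi-mapping read to one random placement
#'
#' Draws uniformly among a read's placements. Each read seeds its own RNG
#' stream from the global seed and a hash of the read id, so the resolution
#' is deterministic and independent of record order.
#'
#' @param records Placement table (one or more reads).
#' @param seed Global integer seed.
#' @return One row per read: the chosen placement (same columns as the
#'   input).
#' @export
resolve_random <- function(records, seed = 42L) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0) return(rec)
  # canonical placement order, so the draw is independent of input order
  data.table::setorder(rec, read_id, chrom, start, strand)
  pick_one <- function(.SD, rid) {
    n <- nrow(.SD)
    if (n == 1L) return(.SD)
    i <- local_seed((hash31(rid) + as.integer(seed)) %% 2147483647L,
                    sample.int(n, 1L))
    .SD[i]
  }
  rec[, pick_one(.SD, .BY[[1]]), by = read_id]
}

#' Write / read the BED6-like placement interchange table
#'
#' One row per placement: `chrom`, `start` (0-based), `end` (exclusive),
#' `read_id`, `n_placements`, `strand` -- BED conventions, so external
#' alignments can be substituted for the internal aligner.
#'
#' @param records Placement table (1-based, from [align_reads()]).
#' @param path Output path.
#' @return `write_placements()`: invisibly, `path`. `read_placements()`: a
#'   placement `data.table` in internal (1-based) coordinates with
#'   `insert_length` and `stratum` recomputed.
#' @export
write_placements <- function(records, path) {
  bed <- data.table::data.table(chrom = records$chrom,
                                start = records$start - 1L,
                                end = records$end,
                                read_id = records$read_id,
                                n_placements = records$n_placements,
                                strand = records$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  bed <- data.table::fread(path, header = FALSE,
                           col.names = .placement_cols)
  out <- data.table::data.table(read_id = bed$read_id,
                                insert_length = bed$end - bed$start,
                                chrom = bed$chrom,
                                start = bed$start + 1L,
                                end = bed$end,
                                strand = bed$strand,
                                n_placements = bed$n_placements)
  out[, stratum := stratum_of(insert_length)]
  out[]
}
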
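#' Adapter trimming policy
#'
#' 3'-anchored adapter matching with substitutions only: a match is either a
#' read suffix equal to a prefix of the adapter (>= `min_overlap` bases) or a
#' full internal adapter occurrence; the leftmost qualifying match and
#' everything 3' of it is removed. Reads with no qualifying match are
#' rejected, as are inserts shorter than `min_length` after trimming.
#'
#' The substitution budget scales with the matched length, mirroring
#' error-rate thresholds of standard adapter trimmers: a match of `m` bases
#' tolerates `min(max_mismatches, m %/% 10)` substitutions, so overlaps
#' shorter than 10 nt must be exact. This keeps chance matches of short read
#' suffixes to the adapter prefix rare.
#'
#' @param adapter_seq 3' adapter sequence (>= 4 nt).
#' @param max_mismatches Cap on allowed substitutions in the adapter match
#'   (default 1).
#' @param min_overlap Minimum adapter bases that must be seen (default 4).
#' @param min_length Minimum retained insert length (default 8).
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                        max_mismatches = 1L, min_overlap = 4L,
                        min_length = 8L) {
  stopifnot(nchar(adapter_seq) >= 4, min_overlap >= 1, min_length >= 1,
            max_mismatches >= 0)
  structure(list(adapter_seq = toupper(adapter_seq),
                 max_mismatches = as.integer(max_mismatches),
                 min_overlap = as.integer(min_overlap),
                 min_length = as.integer(min_length)),
            class = "trim_policy")
}

#' Low-complexity policy
#'
#' A read is low complexity when its longest contiguous single-nucleotide
#' stretch exceeds `max_homopolymer_fraction` of its length (strict
#' inequality; a 12-base run in a 16 nt read, exactly 75%, passes). The
#' alternative reading -- total composition of the most frequent base rather
#' than the longest contiguous run -- is available via
#' `method = "composition"` but is not the default.
#'
#' @param max_homopolymer_fraction Threshold fraction in `(0, 1]`, default 0.75.
#' @param method `"run"` (longest contiguous homopolymer, default) or
#'   `"composition"` (most frequent base fraction).
#' @return An object of class `complexity_policy`.
#' @export
complexity_policy <- function(max_homopolymer_fraction = 0.75,
                              method = c("run", "composition")) {
  stopifnot(max_homopolymer_fraction > 0, max_homopolymer_fraction <= 1)
  structure(list(max_homopolymer_fraction = max_homopolymer_fraction,
                 method = match.arg(method)),
            class = "complexity_policy")
}

# qualifying trim position (leftmost base of the adapter match) per read,
# NA when no match qualifies; vectorized over reads
.trim_positions <- function(seqs, policy) {
  n <- length(seqs)
  len <- nchar(seqs)
  adapter <- policy$adapter_seq
  alen <- nchar(adapter)
  pos <- rep(NA_integer_, n)
  # suffix matches: read suffix of length m vs adapter prefix of length m;
  # larger m = leftmost, so scan m downwards and keep the first hit
  xs <- Biostrings::DNAStringSet(seqs)
  m_hi <- min(alen, max(len))
  for (m in (if (m_hi >= policy$min_overlap) seq(m_hi, policy$min_overlap) else integer())) {
    idx <- which(is.na(pos) & len >= m)
    if (!length(idx)) next
    suff <- Biostrings::subseq(xs[idx], start = len[idx] - m + 1L, width = m)
    # anchored comparison: per-position mismatch count (pattern-matching
    # utilities allow overhangs under max.mismatch, which must not qualify)
    mat <- as.matrix(suff)
    pch <- strsplit(substr(adapter, 1L, m), "")[[1]]
    mm <- rowSums(mat != matrix(pch, nrow(mat), m, byrow = TRUE))
    hit <- mm <= min(policy$max_mismatches, m %/% 10L)
    pos[idx[hit]] <- len[idx[hit]] - m + 1L
  }
  # full internal adapter occurrences (read continues past the adapter);
  # can sit left of any suffix match, so take the minimum. Overhanging
  # pseudo-matches are discarded: the adapter must lie fully inside the read.
  internal <- Biostrings::vmatchPattern(
    adapter, xs, max.mismatch = min(policy$max_mismatches, alen %/% 10L))
  st <- IRanges::start(internal)
  first <- vapply(seq_len(n), function(i) {
    s <- st[[i]]
    s <- s[s >= 1L & s + alen - 1L <= len[i]]
    if (length(s)) min(s) else NA_integer_
  }, integer(1))
  pos <- pmin(pos, first, na.rm = TRUE)
  pos[is.nan(pos)] <- NA_integer_
  as.integer(pos)
}

#' Trim the 3' adapter from read sequences
#'
#' Applies the [trim_policy()] matching rule. In `require_adapter = FALSE`
#' mode (used to check trimming idempotence) reads without an adapter match
#' are returned unchanged instead of rejected.
#'
#' @param seqs Character vector or `DNAStringSet` of read sequences.
#' @param policy A [trim_policy()].
#' @param require_adapter Reject reads with no adapter match (default TRUE).
#' @return A data frame with columns `sequence` (trimmed insert, `NA` when
#'   rejected) and `status` (`"retained"`, `"no_adapter"` or `"too_short"`).
#' @export
trim_adapter <- function(seqs, policy = trim_policy(), require_adapter = TRUE) {
  seqs <- toupper(as.character(seqs))
  stopifnot(all(nchar(seqs) > 0))
  pos <- .trim_positions(seqs, policy)
  insert <- ifelse(is.na(pos), if (require_adapter) NA_character_ else seqs,
                   substr(seqs, 1L, pos - 1L))
  status <- rep("retained", length(seqs))
  status[is.na(insert)] <- "no_adapter"
  too_short <- !is.na(insert) & nchar(insert) < policy$min_length
  status[too_short] <- "too_short"
  insert[too_short] <- NA_character_
  data.frame(sequence = insert, status = status)
}

#' Test sequences for low complexity
#'
#' @param seqs Character vector or `DNAStringSet`.
#' @param policy A [complexity_policy()].
#' @return Logical vector: `TRUE` when the longest homopolymer stretch (or,
#'   under `method = "composition"`, the most frequent base) makes up more
#'   than the threshold fraction of the sequence.
#' @export
is_low_complexity <- function(seqs, policy = complexity_policy()) {
  seqs <- toupper(as.character(seqs))
  stopifnot(all(nchar(seqs) > 0))
  if (policy$method == "composition") {
    frac <- vapply(strsplit(seqs, ""), function(ch) {
      max(table(ch)) / length(ch)
    }, numeric(1))
  } else {
    frac <- vapply(strsplit(seqs, ""), function(ch) {
      max(rle(ch)$lengths) / length(ch)
    }, numeric(1))
  }
  frac > policy$max_homopolymer_fraction
}

#' Apply read-retention rules to a FASTQ file or sequence set
#'
#' Composes the retention rules: 3'-adapter requirement and trimming, minimum
#' insert length, and the low-complexity filter. The returned tally
#' partitions the input: `retained + no_adapter + too_short + low_complexity`
#' always equals the input count.
#'
#' @param input Path to a FASTQ file (gz-transparent), or a named character
#'   vector / `DNAStringSet` of read sequences.
#' @param trim A [trim_policy()].
#' @param complexity A [complexity_policy()].
#' @param min_mean_quality Optional minimum mean Phred quality (default
#'   `NULL`, i.e. the quality filter is a pass-through; synthetic data carry
#'   placeholder qualities). Only available for FASTQ input.
#' @return A list with `inserts` (named character vector of retained trimmed
#'   inserts), `tally` (named integer vector: `input`, `retained`,
#'   `no_adapter`, `too_short`, `low_complexity`, `low_quality`) and
#'   `status` (per-read status vector in input order).
#' @export
preprocess_reads <- function(input, trim = trim_policy(),
                             complexity = complexity_policy(),
                             min_mean_quality = NULL) {
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    parsed <- tryCatch({
      fq <- Biostrings::readDNAStringSet(input, format = "fastq",
                                         with.qualities = TRUE)
      quals <- S4Vectors::mcols(fq)$qualities
      bad <- which(Biostrings::width(quals) != Biostrings::width(fq))
      if (length(bad)) {
        stop("sequence/quality length mismatch at record ", bad[1])
      }
      list(seqs = as.character(fq),
           ids = sub("\\s.*$", "", names(fq)),
           quals = as.character(quals))
    }, error = function(e) stop("malformed FASTQ in ", input, ": ",
                                conditionMessage(e)))
    seqs <- parsed$seqs
    ids <- parsed$ids
    quals <- parsed$quals
  } else {
    seqs <- toupper(as.character(input))
    ids <- names(input) %||% sprintf("read_%06d", seq_along(seqs))
    quals <- NULL
  }
  names(seqs) <- ids
  status <- rep("retained", length(seqs))

  if (!is.null(min_mean_quality) && !is.null(quals)) {
    mq <- vapply(quals, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                 USE.NAMES = FALSE)
    status[mq < min_mean_quality] <- "low_quality"
  }
  keep <- status == "retained"
  tr <- trim_adapter(seqs[keep], trim)
  status[keep] <- tr$status
  inserts <- tr$sequence[tr$status == "retained"]
  names(inserts) <- ids[keep][tr$status == "retained"]
  lc <- is_low_complexity(inserts, complexity)
  status[match(names(inserts)[lc], ids)] <- "low_complexity"
  inserts <- inserts[!lc]

  tally <- c(input = length(seqs),
             retained = sum(status == "retained"),
             no_adapter = sum(status == "no_adapter"),
             too_short = sum(status == "too_short"),
             low_complexity = sum(status == "low_complexity"),
             low_quality = sum(status == "low_quality"))
  stopifnot(tally["input"] == sum(tally[-1]))
  list(inserts = inserts, tally = tally, status = stats::setNames(status, ids))
}
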
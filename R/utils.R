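#' Run code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb the session
#' stream.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic 31-bit hash of a string
#'
#' Polynomial rolling hash used to derive per-read RNG streams from
#' (global seed, read id) so multi-mapping resolution is reproducible and
#' independent of record order.
#'
#' @param x Character vector.
#' @return Integer vector in `[0, 2^31 - 1)`.
#' @keywords internal
hash31 <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Reverse complement of character sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared column order of the placement interchange table (BED6-like,
# 0-based half-open start/end as in BED)
.placement_cols <- c("chrom", "start", "end", "read_id", "n_placements", "strand")
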
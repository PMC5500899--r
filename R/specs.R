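#' Genome simulation parameters
#'
#' Describes the toy genome used by [generate_genome()]: a set of random
#' chromosomes plus a controlled amount of exactly duplicated sequence, which
#' is what makes short (8-12 nt) footprints genuinely multi-map.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in nt (>= 1000).
#' @param repeat_fraction Fraction of the genome covered by duplicated
#'   sequence blocks, in `[0, 0.5]`. Blocks are exact copies: a source
#'   segment inside one feature is copied into a second, distinct feature or
#'   into intergenic space.
#' @param seed Integer RNG seed; identical spec + seed gives byte-identical
#'   output.
#' @return An object of class `genome_spec`.
#' @export
#' @examples
#' genome_spec(n_chromosomes = 1, chromosome_length = 20000, repeat_fraction = 0)
genome_spec <- function(n_chromosomes = 2, chromosome_length = 50000,
                        repeat_fraction = 0.1, seed = 42L) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1000,
            repeat_fraction >= 0, repeat_fraction <= 0.5)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 repeat_fraction = repeat_fraction,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' RNA feature catalogue parameters
#'
#' Per-class feature counts and length ranges for the synthetic annotation.
#' Classes mirror the usual yeast transcript catalogue: a small number of
#' long pre-rRNA-like units, mRNAs, CUTs, SUTs/XUTs, sn/snoRNAs and tRNAs.
#' A fraction of sense features additionally receives an "antisense" twin:
#' an annotation record with identical coordinates on the opposite strand,
#' so the antisense demotion rule of prioritized counting acts on concrete
#' features.
#'
#' @param classes Named list; one entry per class with fields `n` (feature
#'   count) and `len` (length 2 integer vector, min/max feature length in nt).
#' @param antisense_fraction Fraction of sense features that get an
#'   opposite-strand antisense twin.
#' @param abundance_weights Named numeric vector of relative read-sampling
#'   weights per class (>= 0, not all zero). May include the key
#'   `"intergenic"` to sample reads from unannotated space (default absent).
#'   The default is skewed so that the pre-rRNA-like class dominates, as is
#'   typical for exosome-associated RNA.
#' @return An object of class `feature_catalog`.
#' @export
feature_catalog <- function(
    classes = list(
      pre_rRNA  = list(n = 2L,  len = c(3000L, 7000L)),
      mRNA      = list(n = 30L, len = c(500L, 2000L)),
      CUT       = list(n = 10L, len = c(200L, 600L)),
      SUT_XUT   = list(n = 10L, len = c(200L, 800L)),
      sn_snoRNA = list(n = 8L,  len = c(80L, 300L)),
      tRNA      = list(n = 10L, len = c(70L, 120L))
    ),
    antisense_fraction = 0.3,
    abundance_weights = c(pre_rRNA = 0.55, mRNA = 0.20, CUT = 0.06,
                          SUT_XUT = 0.06, sn_snoRNA = 0.06, tRNA = 0.05,
                          antisense = 0.02)) {
  stopifnot(length(classes) >= 1,
            all(vapply(classes, function(x) x$n >= 0 && length(x$len) == 2 &&
                         x$len[1] >= 1 && x$len[2] >= x$len[1], logical(1))),
            antisense_fraction >= 0, antisense_fraction <= 1,
            all(abundance_weights >= 0), any(abundance_weights > 0))
  structure(list(classes = classes,
                 antisense_fraction = antisense_fraction,
                 abundance_weights = abundance_weights),
            class = "feature_catalog")
}

#' Footprint length mixture
#'
#' Protected-fragment lengths are drawn from a mixture of discretized
#' truncated normal components. The shipped default places modes at 10 nt
#' (direct-access-like footprints), a broad 20 nt component, and two minor
#' modes at 39 and 44 nt (channel-plus-helicase-like protection), matching
#' the multi-modal length phenomenology of RNase-protected exosome
#' footprints.
#'
#' @param components Data frame with columns `mode_nt`, `spread_nt`,
#'   `weight`; weights must sum to 1.
#' @param min_nt,max_nt Truncation bounds (inclusive); `min_nt >= 1`.
#' @return An object of class `length_mixture`.
#' @export
length_mixture <- function(
    components = data.frame(
      mode_nt   = c(10, 20, 39, 44),
      spread_nt = c(1.0, 3.0, 1.0, 1.0),
      weight    = c(0.35, 0.45, 0.10, 0.10)),
    min_nt = 8L, max_nt = 50L) {
  stopifnot(is.data.frame(components),
            all(c("mode_nt", "spread_nt", "weight") %in% names(components)),
            abs(sum(components$weight) - 1) < 1e-9,
            all(components$weight >= 0),
            min_nt >= 1, max_nt >= min_nt)
  structure(list(components = components,
                 min_nt = as.integer(min_nt), max_nt = as.integer(max_nt)),
            class = "length_mixture")
}

#' Sample footprint lengths from a mixture
#'
#' @param mixture A [length_mixture()].
#' @param n Number of lengths to draw.
#' @return Integer vector of lengths within the truncation bounds.
#' @export
sample_lengths <- function(mixture, n) {
  comp <- mixture$components
  idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  len <- as.integer(round(stats::rnorm(n, comp$mode_nt[idx], comp$spread_nt[idx])))
  # resample out-of-range draws rather than clamping, to avoid piling mass
  # on the truncation bounds
  bad <- which(len < mixture$min_nt | len > mixture$max_nt)
  while (length(bad) > 0) {
    i2 <- sample.int(nrow(comp), length(bad), replace = TRUE, prob = comp$weight)
    len[bad] <- as.integer(round(stats::rnorm(length(bad), comp$mode_nt[i2],
                                              comp$spread_nt[i2])))
    bad <- bad[len[bad] < mixture$min_nt | len[bad] > mixture$max_nt]
  }
  len
}
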
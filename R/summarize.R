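#' Normalized read-length histogram
#'
#' @param lengths Integer vector of retained insert lengths (>= 1 read), or a
#'   named character vector / `DNAStringSet` of sequences whose lengths are
#'   taken.
#' @return A data frame (`length_nt`, `fraction`) over the full observed
#'   support (missing lengths get fraction 0); fractions sum to 1.
#'   `attr(, "n_reads")` records the read count.
#' @export
length_histogram <- function(lengths) {
  if (!is.numeric(lengths)) lengths <- nchar(as.character(lengths))
  if (length(lengths) == 0) stop("empty input: no reads to histogram")
  support <- seq(min(lengths), max(lengths))
  tab <- tabulate(lengths - min(lengths) + 1L, nbins = length(support))
  out <- data.frame(length_nt = support, fraction = tab / length(lengths))
  attr(out, "n_reads") <- length(lengths)
  out
}

#' Local maxima of a length histogram
#'
#' A length is a local maximum when its fraction exceeds both neighbours
#' (plateaus take the leftmost point) and exceeds `min_fraction`.
#'
#' @param hist Data frame from [length_histogram()].
#' @param min_fraction Ignore maxima below this fraction (default 0.005).
#' @return Integer vector of modal lengths.
#' @export
histogram_modes <- function(hist, min_fraction = 0.005) {
  f <- hist$fraction
  n <- length(f)
  left <- c(-Inf, f[-n])
  right <- c(f[-1], -Inf)
  hist$length_nt[f > left & f >= right & f >= min_fraction]
}

#' Per-feature coverage profile in hits per million mapped reads
#'
#' Coverage at feature base `i` is the number of assigned reads whose
#' placement covers that base, scaled by 10^6 / `total_mapped_reads`. The
#' denominator is stratum-specific (the stratum's mapped total), which is
#' recorded in the output attributes.
#'
#' @param assignments Assignment table from [count_default()] /
#'   [count_prioritized()] (`feature_id`, `chrom`, `start`, `end`, `strand`).
#' @param feature_id Feature to profile (must exist in `features`).
#' @param features `GRanges` annotation.
#' @param total_mapped_reads Normalization total (>= 1).
#' @return A data frame (`feature_id`, `position` 1-based within the feature,
#'   `coverage`), one row per feature base.
#' @export
pileup_profile <- function(assignments, feature_id, features,
                           total_mapped_reads) {
  stopifnot(total_mapped_reads >= 1)
  fid <- S4Vectors::mcols(features)$feature_id
  if (!feature_id %in% fid) stop("unknown feature: ", feature_id)
  feat <- features[fid == feature_id]
  query_id <- feature_id
  asg <- as.data.frame(assignments)
  asg <- asg[!is.na(asg$feature_id) & asg$feature_id == query_id &
               !is.na(asg$start), , drop = FALSE]
  w <- IRanges::width(feat)
  cov <- numeric(w)
  if (nrow(asg)) {
    rel_start <- pmax(asg$start, IRanges::start(feat)) - IRanges::start(feat) + 1L
    rel_end <- pmin(asg$end, IRanges::end(feat)) - IRanges::start(feat) + 1L
    keep <- rel_end >= rel_start & asg$chrom == as.character(
      GenomicRanges::seqnames(feat))
    if (any(keep)) {
      covr <- IRanges::coverage(IRanges::IRanges(rel_start[keep],
                                                 rel_end[keep]), width = w)
      cov <- as.numeric(covr)
    }
  }
  out <- data.frame(feature_id = feature_id, position = seq_len(w),
                    coverage = cov * 1e6 / total_mapped_reads)
  attr(out, "total_mapped_reads") <- total_mapped_reads
  out
}

#' Per-class read fractions and RPKM sums across replicates
#'
#' Read fractions follow the class composition of a single replicate's count
#' table (all classes including `"other"` sum to 1); RPKM sums are computed
#' per class within each replicate, then averaged across replicates with the
#' sample (n-1) standard deviation. A single replicate gets sd 0 by
#' convention, flagged by `n_replicates = 1`.
#'
#' @param count_tables List of count tables (one per replicate) from
#'   [count_default()] / [count_prioritized()], each with matching `mode` and
#'   `stratum`.
#' @param rpkm_tables List of matching RPKM tables from [compute_rpkm()].
#' @param class_map Optional named vector mapping feature classes to display
#'   classes; classes absent from the map are grouped under `"other"` with a
#'   warning. Default: identity.
#' @return A data frame per class: `class`, `mode`, `stratum`,
#'   `read_fraction` (mean across replicates), `rpkm_sum_mean`,
#'   `rpkm_sum_sd`, `n_replicates`.
#' @export
class_summary <- function(count_tables, rpkm_tables, class_map = NULL) {
  stopifnot(length(count_tables) >= 1,
            length(rpkm_tables) == length(count_tables))
  n_rep <- length(count_tables)
  if (!is.null(class_map)) {
    seen <- unique(c(unlist(lapply(count_tables, `[[`, "class")),
                     unlist(lapply(rpkm_tables, `[[`, "class"))))
    missing <- setdiff(seen, names(class_map))
    if (length(missing)) {
      warning("class(es) absent from class_map grouped under 'other': ",
              paste(missing, collapse = ", "))
    }
  }
  map_class <- function(cls) {
    if (is.null(class_map)) return(cls)
    out <- class_map[cls]
    out[is.na(out)] <- "other"
    unname(out)
  }
  frac <- lapply(count_tables, function(ct) {
    dt <- data.table::data.table(class = map_class(ct$class), count = ct$count)
    dt <- dt[, .(count = sum(count)), by = class]
    dt[, read_fraction := count / sum(count)]
    dt
  })
  rsum <- lapply(seq_len(n_rep), function(i) {
    rt <- rpkm_tables[[i]]
    dt <- data.table::data.table(class = map_class(rt$class), rpkm = rt$rpkm)
    dt[, .(rpkm_sum = sum(rpkm)), by = class]
  })
  classes <- sort(unique(c(unlist(lapply(frac, `[[`, "class")),
                           unlist(lapply(rsum, `[[`, "class")))))
  per_class <- function(cl) {
    fr <- vapply(frac, function(d) {
      v <- d$read_fraction[d$class == cl]
      if (length(v)) v else 0
    }, numeric(1))
    rs <- vapply(rsum, function(d) {
      v <- d$rpkm_sum[d$class == cl]
      if (length(v)) v else 0
    }, numeric(1))
    data.frame(class = cl,
               read_fraction = mean(fr),
               rpkm_sum_mean = mean(rs),
               rpkm_sum_sd = if (n_rep > 1) stats::sd(rs) else 0,
               n_replicates = n_rep)
  }
  out <- do.call(rbind, lapply(classes, per_class))
  out$mode <- unique(unlist(lapply(count_tables, function(ct) unique(ct$mode))))[1]
  out$stratum <- unique(unlist(lapply(count_tables, function(ct) unique(ct$stratum))))[1]
  out[, c("class", "mode", "stratum", "read_fraction",
          "rpkm_sum_mean", "rpkm_sum_sd", "n_replicates")]
}
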
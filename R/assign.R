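#' Compute RPKM per feature
#'
#' RPKM = count x 10^9 / (feature length in nt x total mapped reads). The
#' totals are stratum-specific: long-read RPKM is normalized by the long-read
#' mapped total.
#'
#' @param counts Named integer vector of per-feature read counts (the
#'   pseudo-feature `"other"` is ignored if present); features absent from
#'   the vector count 0.
#' @param features `GRanges` annotation with `feature_id` metadata.
#' @param total_mapped_reads Total mapped reads used for normalization (>= 1).
#' @return A data frame (`feature_id`, `class`, `length_nt`, `count`, `rpkm`)
#'   covering every feature, with `total_mapped_reads` as an attribute.
#' @export
compute_rpkm <- function(counts, features, total_mapped_reads) {
  stopifnot(total_mapped_reads >= 1)
  len <- IRanges::width(features)
  if (any(len <= 0)) stop("zero-length feature in annotation")
  fid <- S4Vectors::mcols(features)$feature_id
  cnt <- counts[fid]
  cnt[is.na(cnt)] <- 0
  out <- data.frame(feature_id = fid,
                    class = S4Vectors::mcols(features)$class,
                    length_nt = len,
                    count = as.numeric(cnt),
                    rpkm = as.numeric(cnt) * 1e9 / (len * total_mapped_reads))
  attr(out, "total_mapped_reads") <- total_mapped_reads
  out
}

#' Build the feature priority order from long-read RPKM
#'
#' Features are ranked by descending RPKM (computed from the long-read
#' population), ties broken lexicographically by feature id -- except that
#' every antisense feature is demoted below every non-antisense feature,
#' since short reads aligned antisense are presumed mostly mis-mapped.
#'
#' @param rpkm RPKM table from [compute_rpkm()]; features absent get RPKM 0.
#' @param features `GRanges` annotation (defines the full feature set and
#'   classes).
#' @return A data frame (`rank` starting at 0 = highest priority,
#'   `feature_id`, `class`, `rpkm`).
#' @export
build_priority <- function(rpkm, features) {
  fid <- S4Vectors::mcols(features)$feature_id
  cls <- S4Vectors::mcols(features)$class
  r <- rpkm$rpkm[match(fid, rpkm$feature_id)]
  r[is.na(r)] <- 0
  antisense <- cls == "antisense"
  ord <- order(antisense, -r, fid)
  data.frame(rank = seq_along(fid) - 1L,
             feature_id = fid[ord], class = cls[ord], rpkm = r[ord])
}

# placements (1-based data.table) -> GRanges on the placement strand
.placements_granges <- function(placements) {
  GenomicRanges::GRanges(
    seqnames = placements$chrom,
    ranges = IRanges::IRanges(start = placements$start, end = placements$end),
    strand = placements$strand)
}

#' Features overlapping a set of placements
#'
#' Same-strand overlap of at least `min_overlap_nt` bases. Antisense
#' annotation records live on the physical strand opposite their sense twin,
#' so an opposite-strand hit surfaces as an antisense-class feature.
#'
#' @param placements Placement table (1-based; rows from [align_reads()]).
#' @param features `GRanges` annotation with `feature_id` and `class`.
#' @param min_overlap_nt Minimum overlap in nt (default 1: any intersection).
#' @return A `data.table` mapping placement rows to features:
#'   `placement_row`, `read_id`, `feature_id`, `class`.
#' @export
overlapping_features <- function(placements, features, min_overlap_nt = 1L) {
  gr <- .placements_granges(placements)
  ov <- GenomicRanges::findOverlaps(gr, features,
                                    minoverlap = min_overlap_nt,
                                    ignore.strand = FALSE)
  data.table::data.table(
    placement_row = S4Vectors::queryHits(ov),
    read_id = placements$read_id[S4Vectors::queryHits(ov)],
    feature_id = S4Vectors::mcols(features)$feature_id[S4Vectors::subjectHits(ov)],
    class = S4Vectors::mcols(features)$class[S4Vectors::subjectHits(ov)])
}

# internal: finish a count table, enforcing the conservation invariant
.finish_counts <- function(assign_dt, n_reads, features, mode, stratum) {
  counts <- assign_dt[, .N, by = feature_id]
  cls_map <- stats::setNames(S4Vectors::mcols(features)$class,
                             S4Vectors::mcols(features)$feature_id)
  out <- data.frame(feature_id = counts$feature_id,
                    class = ifelse(counts$feature_id == "other", "other",
                                   cls_map[counts$feature_id]),
                    count = counts$N,
                    mode = mode, stratum = stratum)
  stopifnot(sum(out$count) == n_reads)
  attr(out, "n_reads") <- n_reads
  out
}

#' Default-mode counting: random placement, no RPKM ranking
#'
#' Each read is resolved to a single random placement
#' ([resolve_random()]); among the features overlapping that placement it is
#' assigned to one under a fixed arbitrary order (lexicographic feature id).
#' Reads whose chosen placement overlaps nothing are counted as `"other"`.
#'
#' @param records Placement table for one stratum.
#' @param features `GRanges` annotation.
#' @param seed Global seed for random placement resolution.
#' @param min_overlap_nt Minimum overlap in nt.
#' @return A list: `counts` (count table data frame with pseudo-feature
#'   `"other"`; `sum(count)` equals the number of counted reads) and
#'   `assignments` (`read_id`, `feature_id`, plus the chosen placement).
#' @export
count_default <- function(records, features, seed = 42L, min_overlap_nt = 1L) {
  rec <- data.table::as.data.table(records)
  stratum <- if (nrow(rec)) unique(rec$stratum)[1] else NA_character_
  chosen <- resolve_random(rec, seed)
  if (nrow(chosen) == 0) {
    empty <- data.frame(feature_id = character(), class = character(),
                        count = integer(), mode = character(),
                        stratum = character())
    return(list(counts = empty,
                assignments = data.table::data.table(read_id = character(),
                                                     feature_id = character())))
  }
  chosen[, placement_row := .I]
  ov <- overlapping_features(chosen, features, min_overlap_nt)
  best <- ov[order(feature_id), .SD[1], by = read_id]
  asg <- data.table::data.table(read_id = chosen$read_id)
  asg[, feature_id := best$feature_id[match(read_id, best$read_id)]]
  asg[is.na(feature_id), feature_id := "other"]
  asg <- cbind(asg, chosen[, .(chrom, start, end, strand, insert_length)])
  list(counts = .finish_counts(asg, nrow(chosen), features, "default", stratum),
       assignments = asg)
}

#' Prioritized counting: multi-mapping rescue by long-read RPKM rank
#'
#' For each read, the features overlapping ALL of its candidate placements
#' are pooled and the read is counted to the pooled feature with the best
#' (lowest) rank in the priority list. Reads overlapping no feature at any
#' placement fall back to `"other"`. The function is deterministic: no RNG is
#' involved.
#'
#' With `scope = "placement"` the read is first resolved to one random
#' placement and the rank decides only among that placement's features;
#' this variant cannot move a read between loci and is provided for
#' comparison.
#'
#' @param records Placement table for one stratum.
#' @param features `GRanges` annotation.
#' @param priority Priority list from [build_priority()] (must cover every
#'   feature; a pooled feature missing from it is an error).
#' @param scope `"pooled"` (default) or `"placement"`.
#' @param seed Seed, used only under `scope = "placement"`.
#' @param min_overlap_nt Minimum overlap in nt.
#' @return A list: `counts` (count table with `"other"`) and `assignments`
#'   (`read_id`, `feature_id`, and the placement consistent with the
#'   assignment: the placement inside the winning feature with the
#'   lexicographically smallest start).
#' @export
count_prioritized <- function(records, features, priority,
                              scope = c("pooled", "placement"),
                              seed = 42L, min_overlap_nt = 1L) {
  scope <- match.arg(scope)
  rec <- data.table::as.data.table(records)
  stratum <- if (nrow(rec)) unique(rec$stratum)[1] else NA_character_
  if (scope == "placement") rec <- resolve_random(rec, seed)
  if (nrow(rec) == 0) {
    empty <- data.frame(feature_id = character(), class = character(),
                        count = integer(), mode = character(),
                        stratum = character())
    return(list(counts = empty,
                assignments = data.table::data.table(read_id = character(),
                                                     feature_id = character())))
  }
  rec[, placement_row := .I]
  ov <- overlapping_features(rec, features, min_overlap_nt)
  if (nrow(ov)) {
    rk <- priority$rank[match(ov$feature_id, priority$feature_id)]
    if (anyNA(rk)) {
      stop("feature(s) missing from priority list: ",
           paste(unique(ov$feature_id[is.na(rk)]), collapse = ", "))
    }
    ov[, rank := rk]
    ov[, start := rec$start[placement_row]]
    ov[, end := rec$end[placement_row]]
    ov[, chrom := rec$chrom[placement_row]]
    ov[, strand := rec$strand[placement_row]]
    ov[, insert_length := rec$insert_length[placement_row]]
    best <- ov[order(rank, start, chrom), .SD[1], by = read_id]
  } else {
    best <- data.table::data.table(read_id = character(),
                                   feature_id = character())
  }
  all_ids <- unique(rec$read_id)
  asg <- data.table::data.table(read_id = all_ids)
  m <- match(all_ids, best$read_id)
  asg[, feature_id := ifelse(is.na(m), "other", best$feature_id[m])]
  for (col in c("chrom", "start", "end", "strand", "insert_length")) {
    asg[[col]] <- if (nrow(best)) best[[col]][m] else NA
  }
  # "other" reads keep their first placement so pileups stay well-defined
  noov <- which(is.na(m))
  if (length(noov)) {
    firstp <- rec[!duplicated(read_id)]
    fm <- match(all_ids[noov], firstp$read_id)
    for (col in c("chrom", "start", "end", "strand", "insert_length")) {
      asg[[col]][noov] <- firstp[[col]][fm]
    }
  }
  list(counts = .finish_counts(asg, length(all_ids), features,
                               paste0("prioritized_", scope), stratum),
       assignments = asg)
}

#' Write a count table with its normalization header
#'
#' @param counts Count table from [count_default()] / [count_prioritized()].
#' @param rpkm Optional RPKM table to join in.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, rpkm = NULL) {
  out <- counts
  if (!is.null(rpkm)) {
    out$rpkm <- rpkm$rpkm[match(out$feature_id, rpkm$feature_id)]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cracr counts; mode=", unique(counts$mode),
                    " stratum=", unique(counts$stratum),
                    "; RPKM totals are stratum-specific"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
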
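#' Generate a toy genome with annotated features and exact repeat blocks
#'
#' Builds random chromosomes, packs a strand-specific feature catalogue into
#' them without same-strand overlap, adds antisense twins (identical
#' coordinates, opposite strand, class `"antisense"`), and finally copies
#' exact sequence blocks between distinct features (or a feature and
#' intergenic space) until the requested fraction of the genome is covered by
#' duplicated sequence. The duplicated blocks are what make short footprints
#' genuinely ambiguous to place.
#'
#' @param spec A [genome_spec()].
#' @param catalog A [feature_catalog()].
#' @return A list with elements:
#'   * `genome`: named [Biostrings::DNAStringSet] of chromosomes;
#'   * `features`: [GenomicRanges::GRanges] with metadata columns
#'     `feature_id` and `class` (1-based closed coordinates);
#'   * `repeats`: data frame registry of duplicated blocks
#'     (`block_id`, `length`, `src_chrom`, `src_start`, `dest_chrom`,
#'     `dest_start`, 1-based).
#' @export
generate_genome <- function(spec, catalog) {
  stopifnot(inherits(spec, "genome_spec"), inherits(catalog, "feature_catalog"))
  local_seed(spec$seed, {
    chrom_names <- paste0("chr", seq_len(spec$n_chromosomes))
    L <- spec$chromosome_length
    chroms <- vapply(chrom_names, function(nm) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))

    # -- pack features, largest first, into per-chromosome free intervals ----
    want <- do.call(rbind, lapply(names(catalog$classes), function(cl) {
      spec_cl <- catalog$classes[[cl]]
      if (spec_cl$n == 0) return(NULL)
      data.frame(class = cl,
                 len = sample(seq(spec_cl$len[1], spec_cl$len[2]),
                              spec_cl$n, replace = TRUE))
    }))
    want <- want[order(-want$len), , drop = FALSE]
    free <- lapply(chrom_names, function(nm) data.frame(start = 1L, end = L))
    names(free) <- chrom_names
    placed <- vector("list", nrow(want))
    for (i in seq_len(nrow(want))) {
      len <- want$len[i]
      cand <- do.call(rbind, lapply(chrom_names, function(nm) {
        f <- free[[nm]]
        f <- f[f$end - f$start + 1L >= len, , drop = FALSE]
        if (nrow(f) == 0) return(NULL)
        cbind(chrom = nm, f)
      }))
      if (is.null(cand) || nrow(cand) == 0) {
        stop("infeasible packing: feature catalogue (",
             sum(want$len), " nt of features) exceeds free chromosome ",
             "capacity while placing a ", len, " nt ", want$class[i],
             " feature")
      }
      w <- cand$end - cand$start + 1L - len + 1L
      j <- sample.int(nrow(cand), 1, prob = w)
      start <- cand$start[j] + sample.int(w[j], 1) - 1L
      placed[[i]] <- data.frame(chrom = cand$chrom[j], start = start,
                                end = start + len - 1L, class = want$class[i],
                                strand = sample(c("+", "-"), 1))
      # split the free interval around the new feature
      f <- free[[cand$chrom[j]]]
      k <- which(f$start == cand$start[j] & f$end == cand$end[j])
      pieces <- data.frame(start = c(f$start[k], start + len),
                           end = c(start - 1L, f$end[k]))
      pieces <- pieces[pieces$end >= pieces$start, , drop = FALSE]
      free[[cand$chrom[j]]] <- rbind(f[-k, , drop = FALSE], pieces)
    }
    feat <- do.call(rbind, placed)
    feat <- feat[order(feat$chrom, feat$start), , drop = FALSE]
    cls_n <- stats::ave(seq_len(nrow(feat)), feat$class, FUN = seq_along)
    feat$feature_id <- sprintf("%s_%03d", feat$class, cls_n)

    # -- antisense twins: identical coordinates, opposite strand -------------
    n_as <- floor(catalog$antisense_fraction * nrow(feat))
    if (n_as > 0) {
      twin <- feat[sample.int(nrow(feat), n_as), , drop = FALSE]
      twin$strand <- ifelse(twin$strand == "+", "-", "+")
      twin$feature_id <- paste0("antisense_", twin$feature_id)
      twin$class <- "antisense"
      feat <- rbind(feat, twin)
    }

    # -- repeat blocks: exact copies between distinct features/intergenic ----
    total_len <- spec$n_chromosomes * L
    target_cov <- spec$repeat_fraction * total_len
    sense <- feat[feat$class != "antisense", , drop = FALSE]
    gaps <- do.call(rbind, lapply(chrom_names, function(nm) {
      f <- free[[nm]]
      if (nrow(f) == 0) return(NULL)
      cbind(chrom = nm, f)
    }))
    repeats <- list()
    used <- data.frame(chrom = character(), start = integer(), end = integer())
    cov <- 0
    attempts <- 0
    while (cov < target_cov) {
      attempts <- attempts + 1
      if (attempts > 50 * max(1, ceiling(target_cov / 40))) {
        stop("infeasible packing: cannot place enough repeat blocks to reach ",
             "repeat_fraction = ", spec$repeat_fraction,
             " without overlapping previous blocks")
      }
      blen <- sample(20:40, 1)
      src_ok <- sense[sense$end - sense$start + 1L >= blen, , drop = FALSE]
      if (nrow(src_ok) < 2) stop("infeasible packing: fewer than two features can hold a repeat block")
      si <- sample.int(nrow(src_ok), 1)
      src <- src_ok[si, ]
      s_start <- src$start + sample.int(src$end - src$start + 1L - blen + 1L, 1) - 1L
      # destination: a different feature, or (20% of draws) an intergenic gap
      use_gap <- !is.null(gaps) && nrow(gaps[gaps$end - gaps$start + 1L >= blen, ]) > 0 &&
        stats::runif(1) < 0.2
      if (use_gap) {
        g <- gaps[gaps$end - gaps$start + 1L >= blen, , drop = FALSE]
        gi <- sample.int(nrow(g), 1)
        d_chrom <- g$chrom[gi]
        d_start <- g$start[gi] + sample.int(g$end[gi] - g$start[gi] + 1L - blen + 1L, 1) - 1L
      } else {
        dst_ok <- src_ok[src_ok$feature_id != src$feature_id, , drop = FALSE]
        di <- sample.int(nrow(dst_ok), 1)
        dst <- dst_ok[di, ]
        d_chrom <- dst$chrom
        d_start <- dst$start + sample.int(dst$end - dst$start + 1L - blen + 1L, 1) - 1L
      }
      # keep blocks disjoint from one another so each stays an exact pair
      new <- data.frame(chrom = c(src$chrom, d_chrom),
                        start = c(s_start, d_start),
                        end = c(s_start + blen - 1L, d_start + blen - 1L))
      clash <- any(vapply(seq_len(nrow(used)), function(u) {
        any(used$chrom[u] == new$chrom & used$start[u] <= new$end &
              used$end[u] >= new$start)
      }, logical(1))) ||
        (new$chrom[1] == new$chrom[2] && new$start[1] <= new$end[2] &&
           new$end[1] >= new$start[2])
      if (clash) next
      block <- substr(chroms[[src$chrom]], s_start, s_start + blen - 1L)
      substr(chroms[[d_chrom]], d_start, d_start + blen - 1L) <- block
      used <- rbind(used, new)
      repeats[[length(repeats) + 1L]] <- data.frame(
        block_id = length(repeats) + 1L, length = blen,
        src_chrom = src$chrom, src_start = s_start,
        dest_chrom = d_chrom, dest_start = d_start)
      cov <- cov + 2L * blen
    }
    repeats <- if (length(repeats)) do.call(rbind, repeats) else
      data.frame(block_id = integer(), length = integer(),
                 src_chrom = character(), src_start = integer(),
                 dest_chrom = character(), dest_start = integer())

    genome <- Biostrings::DNAStringSet(chroms)
    names(genome) <- chrom_names
    gr <- GenomicRanges::GRanges(
      seqnames = feat$chrom,
      ranges = IRanges::IRanges(start = feat$start, end = feat$end),
      strand = feat$strand,
      feature_id = feat$feature_id, class = feat$class,
      seqlengths = stats::setNames(rep(L, spec$n_chromosomes), chrom_names))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    list(genome = genome, features = gr, repeats = repeats)
  })
}

#' Simulate RNase-protected footprint reads with ground truth
#'
#' Samples a source class proportionally to `abundance_weights`, a feature
#' uniformly within the class, a protected length from the mixture
#' (resampling lengths that do not fit inside the feature), and a uniform
#' start within the feature. The read sequence is the genomic substring,
#' reverse-complemented for minus-strand features. Every read gets a truth
#' row recording its provenance, which downstream mis-assignment rates are
#' measured against.
#'
#' @param genome Named `DNAStringSet` of chromosomes.
#' @param features `GRanges` annotation with `feature_id` and `class`.
#' @param mixture A [length_mixture()].
#' @param abundance_weights Named per-class sampling weights (see
#'   [feature_catalog()]); classes absent from the annotation are dropped
#'   with a warning. The key `"intergenic"` samples from unannotated space.
#' @param n_reads Number of reads (>= 1).
#' @param seed Integer RNG seed.
#' @return A list with `reads` (named `DNAStringSet` of inserts) and `truth`
#'   (data frame: `read_id`, `feature_id`, `class`, `chrom`, `start` (1-based),
#'   `strand`, `length`). The number of length re-draws forced by short
#'   features is attached as `attr(truth, "n_length_resampled")`.
#' @export
simulate_reads <- function(genome, features, mixture, abundance_weights,
                           n_reads, seed = 42L) {
  stopifnot(n_reads >= 1)
  fclass <- S4Vectors::mcols(features)$class
  have <- c(unique(fclass), "intergenic")
  w <- abundance_weights[names(abundance_weights) %in% have]
  if (length(w) < length(abundance_weights)) {
    warning("dropping abundance weights for classes absent from annotation: ",
            paste(setdiff(names(abundance_weights), have), collapse = ", "))
  }
  stopifnot(sum(w) > 0)
  if (is.na(w["intergenic"])) w <- w[names(w) != "intergenic"]

  chrom_str <- as.character(genome)
  # intergenic gaps: unannotated on both strands
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(features, ignore.strand = TRUE))
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]

  local_seed(seed, {
    cls <- sample(names(w), n_reads, replace = TRUE, prob = w)
    len <- sample_lengths(mixture, n_reads)
    out <- data.table::data.table(
      read_id = sprintf("read_%06d", seq_len(n_reads)),
      class = cls, length = len,
      feature_id = NA_character_, chrom = NA_character_,
      start = NA_integer_, strand = NA_character_)
    n_resampled <- 0L
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      if (cl == "intergenic") {
        ok <- IRanges::width(gaps) >= out$length[idx]
        # gaps are plentiful; resample lengths that fit nowhere
        maxgap <- max(IRanges::width(gaps))
        while (any(out$length[idx] > maxgap)) {
          bad <- idx[out$length[idx] > maxgap]
          n_resampled <- n_resampled + length(bad)
          out$length[bad] <- sample_lengths(mixture, length(bad))
        }
        gi <- vapply(out$length[idx], function(l) {
          cand <- which(IRanges::width(gaps) >= l)
          cand[sample.int(length(cand), 1, prob = IRanges::width(gaps)[cand])]
        }, integer(1))
        g <- gaps[gi]
        off <- floor(stats::runif(length(idx)) *
                       (IRanges::width(g) - out$length[idx] + 1L))
        out$feature_id[idx] <- "intergenic"
        out$chrom[idx] <- as.character(GenomicRanges::seqnames(g))
        out$start[idx] <- IRanges::start(g) + as.integer(off)
        out$strand[idx] <- sample(c("+", "-"), length(idx), replace = TRUE)
      } else {
        fi <- which(fclass == cl)
        pick <- fi[sample.int(length(fi), length(idx), replace = TRUE)]
        fw <- IRanges::width(features)[pick]
        # footprint must fit inside the feature: resample the length
        bad <- which(out$length[idx] > fw)
        tries <- 0L
        while (length(bad) > 0) {
          tries <- tries + 1L
          if (tries > 1000L) {
            stop("a ", cl, " feature is shorter than every length the ",
                 "mixture can produce")
          }
          n_resampled <- n_resampled + length(bad)
          out$length[idx[bad]] <- sample_lengths(mixture, length(bad))
          bad <- bad[out$length[idx[bad]] > fw[bad]]
        }
        off <- floor(stats::runif(length(idx)) *
                       (fw - out$length[idx] + 1L))
        out$feature_id[idx] <- S4Vectors::mcols(features)$feature_id[pick]
        out$chrom[idx] <- as.character(GenomicRanges::seqnames(features))[pick]
        out$start[idx] <- IRanges::start(features)[pick] + as.integer(off)
        out$strand[idx] <- as.character(GenomicRanges::strand(features))[pick]
      }
    }
    seqs <- character(n_reads)
    for (cm in unique(out$chrom)) {
      ii <- which(out$chrom == cm)
      seqs[ii] <- substring(chrom_str[[cm]], out$start[ii],
                            out$start[ii] + out$length[ii] - 1L)
    }
    minus <- which(out$strand == "-")
    if (length(minus)) seqs[minus] <- revcomp(seqs[minus])
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- out$read_id
    truth <- as.data.frame(out[, c("read_id", "feature_id", "class", "chrom",
                                   "start", "strand", "length")])
    if (n_resampled > 0) {
      message(n_resampled, " footprint length draw(s) exceeded their source ",
              "feature and were resampled")
    }
    attr(truth, "n_length_resampled") <- n_resampled
    list(reads = reads, truth = truth)
  })
}

#' Append 3' sequencing adapters and emit FASTQ records
#'
#' With probability `adapter_present_prob` the 3' adapter (possibly carrying
#' random substitution errors at `per_base_error_rate`) is appended to each
#' insert; reads without the adapter model inserts running into the read
#' length limit, which the preprocessing stage must reject. Base qualities
#' are a constant placeholder (`"I"`).
#'
#' @param reads Named `DNAStringSet` of inserts (e.g. from [simulate_reads()]).
#' @param adapter_seq Adapter sequence (>= 4 nt). Default is the standard
#'   small-RNA 3' linker.
#' @param adapter_present_prob Probability a read carries the adapter.
#' @param per_base_error_rate Per-base substitution rate within the adapter.
#' @param seed Integer RNG seed.
#' @return A list with `sequences` (named `DNAStringSet`, insert + adapter),
#'   `qualities` (`BStringSet`), and `has_adapter` (logical vector).
#' @export
attach_adapters <- function(reads, adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                            adapter_present_prob = 0.9,
                            per_base_error_rate = 0.01, seed = 42L) {
  stopifnot(nchar(adapter_seq) >= 4,
            adapter_present_prob >= 0, adapter_present_prob <= 1,
            per_base_error_rate >= 0, per_base_error_rate <= 1)
  n <- length(reads)
  alen <- nchar(adapter_seq)
  local_seed(seed, {
    has <- stats::runif(n) < adapter_present_prob
    adapters <- rep(adapter_seq, sum(has))
    if (per_base_error_rate > 0 && sum(has) > 0) {
      err <- which(matrix(stats::runif(sum(has) * alen) < per_base_error_rate,
                          nrow = sum(has)), arr.ind = TRUE)
      bases <- c("A", "C", "G", "T")
      for (r in seq_len(nrow(err))) {
        i <- err[r, 1]; p <- err[r, 2]
        cur <- substr(adapters[i], p, p)
        substr(adapters[i], p, p) <- sample(setdiff(bases, cur), 1)
      }
    }
    seqs <- as.character(reads)
    seqs[has] <- paste0(seqs[has], adapters)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(reads)
    quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    names(quals) <- names(reads)
    list(sequences = out, qualities = quals, has_adapter = has)
  })
}

#' Run the full default simulation
#'
#' Convenience wrapper generating the shipped default study conditions:
#' genome, annotation, repeat registry, footprint reads with truth, and
#' adapter-bearing FASTQ-ready sequences.
#'
#' @param spec,catalog,mixture Simulation parameter objects; defaults are the
#'   shipped study conditions.
#' @param n_reads Number of reads.
#' @param seed Integer seed used for every random stage.
#' @inheritParams attach_adapters
#' @return A list: `genome`, `features`, `repeats`, `reads`, `truth`,
#'   `fastq` (output of [attach_adapters()]).
#' @export
simulate_crac_dataset <- function(spec = genome_spec(),
                                  catalog = feature_catalog(),
                                  mixture = length_mixture(),
                                  n_reads = 50000L, seed = 42L,
                                  adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                                  adapter_present_prob = 0.9,
                                  per_base_error_rate = 0.01) {
  spec$seed <- as.integer(seed)
  gen <- generate_genome(spec, catalog)
  sim <- simulate_reads(gen$genome, gen$features, mixture,
                        catalog$abundance_weights, n_reads, seed = seed + 1L)
  fq <- attach_adapters(sim$reads, adapter_seq, adapter_present_prob,
                        per_base_error_rate, seed = seed + 2L)
  c(gen, sim, list(fastq = fq, adapter_seq = adapter_seq))
}

#' Write simulation outputs to standard formats
#'
#' Writes genome FASTA, annotation GFF3 (1-based inclusive; `type` column is
#' the RNA class, attributes carry `ID` and `class`), reads FASTQ, the truth
#' table TSV (1-based starts) and the repeat-block registry TSV.
#'
#' @param sim Output of [simulate_crac_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "features.gff3"),
             reads = file.path(dir, "reads.fastq"),
             truth = file.path(dir, "truth.tsv"),
             repeats = file.path(dir, "repeats.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_annotation(sim$features, paths["annotation"])
  Biostrings::writeXStringSet(sim$fastq$sequences, paths["reads"],
                              format = "fastq",
                              qualities = sim$fastq$qualities)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$repeats, paths["repeats"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write / read the feature annotation as GFF3
#'
#' @param features `GRanges` with `feature_id` and `class` metadata columns.
#' @param path Output path.
#' @return `write_annotation()`: invisibly, `path`. `read_annotation()`: a
#'   `GRanges` with `feature_id` and `class`.
#' @export
write_annotation <- function(features, path) {
  gr <- features
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "cracr",
    type = S4Vectors::mcols(features)$class,
    ID = S4Vectors::mcols(features)$feature_id,
    class = S4Vectors::mcols(features)$class)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = S4Vectors::mcols(gr)$ID,
    class = as.character(S4Vectors::mcols(gr)$class %||%
                           S4Vectors::mcols(gr)$type))
  gr
}
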
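make_features <- function(ids, classes, starts, ends, strands = "+",
                          chrom = "chr1") {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(starts, ends),
                         strand = strands, feature_id = ids, class = classes)
}

test_that("RPKM follows count x 1e9 / (length x total)", {
  f <- make_features(c("A", "B", "C"), c("mRNA", "mRNA", "CUT"),
                     c(1, 2001, 4001), c(1000, 2500, 4001 + 499))
  r <- compute_rpkm(c(A = 100, C = 50), f, 1e6)
  expect_equal(r$rpkm[r$feature_id == "A"], 100)
  expect_equal(r$rpkm[r$feature_id == "B"], 0)
  r2 <- compute_rpkm(c(C = 50), f, 2e6)
  expect_equal(r2$rpkm[r2$feature_id == "C"], 50)

  zero <- make_features("Z", "mRNA", 10, 9)  # zero width
  expect_error(compute_rpkm(c(Z = 1), zero, 1e6), "zero-length")
})

test_that("priority ranks by RPKM with antisense demoted below everything", {
  f <- make_features(c("A", "B", "C"), c("mRNA", "CUT", "antisense"),
                     c(1, 101, 201), c(50, 150, 250))
  rpkm <- data.frame(feature_id = c("A", "B", "C"),
                     rpkm = c(10, 100, 500))
  p <- build_priority(rpkm, f)
  expect_identical(p$feature_id, c("B", "A", "C"))
  expect_identical(p$rank, 0:2)

  # equal RPKM: lexicographic within the sense block; zero data likewise
  tie <- data.frame(feature_id = c("A", "B", "C"), rpkm = c(1, 1, 1))
  expect_identical(build_priority(tie, f)$feature_id, c("A", "B", "C"))
  none <- data.frame(feature_id = character(), rpkm = numeric())
  expect_identical(build_priority(none, f)$feature_id, c("A", "B", "C"))
})

fix_features <- make_features(
  c("mRNA_A", "antisense_mRNA_A", "CUT_B"),
  c("mRNA", "antisense", "CUT"),
  c(51, 51, 251), c(200, 200, 330), strands = c("+", "-", "+"))

placement <- function(read_id, start, end, strand = "+", chrom = "chr1",
                      n = 1L) {
  data.table::data.table(read_id = read_id,
                         insert_length = end - start + 1L,
                         chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         n_placements = n,
                         stratum = stratum_of(end - start + 1L))
}

test_that("overlap predicate is strand-specific with antisense twins surfacing", {
  p <- rbind(placement("r1", 100, 109, "+"),
             placement("r2", 100, 109, "-"),
             placement("r3", 10, 19, "+"))
  ov <- overlapping_features(p, fix_features)
  expect_identical(ov$feature_id[ov$read_id == "r1"], "mRNA_A")
  expect_identical(ov$feature_id[ov$read_id == "r2"], "antisense_mRNA_A")
  expect_false("r3" %in% ov$read_id)
})

test_that("default counting assigns one placement and conserves reads", {
  p <- placement("r1", 100, 109, "+")
  res <- count_default(p, fix_features, seed = 1)
  expect_identical(res$counts$feature_id, "mRNA_A")
  expect_identical(res$counts$count, 1L)

  empty <- placement(character(0), integer(0), integer(0))
  expect_identical(nrow(count_default(empty, fix_features)$counts), 0L)

  # binomial oracle: 1e4 reads, 2 equiprobable placements (mRNA vs intergenic)
  n <- 10000L
  p2 <- data.table::rbindlist(lapply(sprintf("r%05d", 1:n), function(id) {
    rbind(placement(id, 100, 109, "+", n = 2L),
          placement(id, 10, 19, "+", n = 2L))
  }))
  res2 <- count_default(p2, fix_features, seed = 3)
  x <- res2$counts$count[res2$counts$feature_id == "mRNA_A"]
  expect_lt(abs(x - n / 2), 3 * sqrt(n * 0.25))
  expect_identical(sum(res2$counts$count), n)
})

test_that("prioritized counting assigns the best-ranked pooled feature", {
  priority <- data.frame(rank = 0:2,
                         feature_id = c("mRNA_A", "CUT_B", "antisense_mRNA_A"),
                         class = c("mRNA", "CUT", "antisense"),
                         rpkm = c(100, 10, 500))
  # two placements hitting a high-rank and a low-rank feature: high wins
  p <- rbind(placement("r1", 100, 109, "+", n = 2L),
             placement("r1", 260, 269, "+", n = 2L))
  res <- count_prioritized(p, fix_features, priority)
  expect_identical(res$counts$feature_id, "mRNA_A")

  # antisense vs sense at different loci: sense wins despite higher RPKM
  p2 <- rbind(placement("r2", 100, 109, "-", n = 2L),
              placement("r2", 260, 269, "+", n = 2L))
  res2 <- count_prioritized(p2, fix_features, priority)
  expect_identical(res2$counts$feature_id, "CUT_B")

  # no overlap anywhere: "other"
  p3 <- placement("r3", 10, 19, "+")
  res3 <- count_prioritized(p3, fix_features, priority)
  expect_identical(res3$counts$feature_id, "other")

  # an overlapping feature missing from the priority list is an error
  expect_error(count_prioritized(p, fix_features, priority[-1, ]),
               "missing from priority")
})

test_that("prioritized counting is deterministic and conserves reads", {
  fix <- tiny_fixture(duplicate_block = TRUE)
  idx <- build_kmer_index(fix$genome, k = 8)
  sim <- simulate_reads(fix$genome, fix$features, length_mixture(),
                        c(mRNA = 0.6, CUT = 0.3, antisense = 0.1), 200,
                        seed = 51)
  hits <- align_reads(sim$reads, idx)
  strata <- stratify_reads(hits)
  priority <- build_priority(
    compute_rpkm(c(mRNA_A = 50, CUT_B = 10), fix$features, 100),
    fix$features)
  for (st in c("short", "long")) {
    a <- count_prioritized(strata[[st]], fix$features, priority)
    b <- count_prioritized(strata[[st]], fix$features, priority)
    expect_identical(a$counts, b$counts)
    expect_identical(sum(a$counts$count),
                     length(unique(strata[[st]]$read_id)))
    d <- count_default(strata[[st]], fix$features, seed = 52)
    expect_identical(sum(d$counts$count),
                     length(unique(strata[[st]]$read_id)))
  }
})

test_that("unique-mapping long reads are counted identically in both modes", {
  fix <- tiny_fixture()  # no duplicated block: long reads map uniquely
  idx <- build_kmer_index(fix$genome, k = 8)
  sim <- simulate_reads(fix$genome, fix$features, length_mixture(),
                        c(mRNA = 0.7, CUT = 0.3), 150, seed = 53)
  hits <- align_reads(sim$reads, idx)
  long <- stratify_reads(hits)$long
  expect_true(all(long$n_placements == 1))
  priority <- build_priority(
    compute_rpkm(c(mRNA_A = 5, CUT_B = 50), fix$features, 10), fix$features)
  d <- count_default(long, fix$features, seed = 54)$counts
  p <- count_prioritized(long, fix$features, priority)$counts
  expect_identical(d[order(d$feature_id), c("feature_id", "count")],
                   p[order(p$feature_id), c("feature_id", "count")])
})

test_that("count tables match a brute-force recount", {
  fix <- tiny_fixture(duplicate_block = TRUE)
  idx <- build_kmer_index(fix$genome, k = 8)
  sim <- simulate_reads(fix$genome, fix$features, length_mixture(),
                        c(mRNA = 0.5, CUT = 0.4, antisense = 0.1), 250,
                        seed = 55)
  hits <- align_reads(sim$reads, idx)
  fdf <- feature_df(fix$features)
  priority <- build_priority(
    compute_rpkm(c(mRNA_A = 50, CUT_B = 10), fix$features, 100), fix$features)

  short <- stratify_reads(hits)$short
  pr <- count_prioritized(short, fix$features, priority)$counts
  oracle_p <- oracle_count_prioritized(as.data.frame(short), fdf, priority)
  expect_identical(stats::setNames(pr$count, pr$feature_id)[names(oracle_p)],
                   stats::setNames(as.integer(oracle_p), names(oracle_p)))

  de <- count_default(short, fix$features, seed = 56)
  chosen <- resolve_random(short, seed = 56)
  oracle_d <- oracle_count_default(as.data.frame(chosen), fdf)
  expect_identical(stats::setNames(de$counts$count,
                                   de$counts$feature_id)[names(oracle_d)],
                   stats::setNames(as.integer(oracle_d), names(oracle_d)))
})
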
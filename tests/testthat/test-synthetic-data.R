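test_that("genome generation is deterministic, byte for byte", {
  spec <- genome_spec(n_chromosomes = 1, chromosome_length = 20000,
                      repeat_fraction = 0.05, seed = 1L)
  g1 <- generate_genome(spec, small_catalog())
  g2 <- generate_genome(spec, small_catalog())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(feature_df(g1$features), feature_df(g2$features))
  expect_identical(g1$repeats, g2$repeats)

  s1 <- simulate_reads(g1$genome, g1$features, length_mixture(),
                       small_catalog()$abundance_weights, 200, seed = 5)
  s2 <- simulate_reads(g1$genome, g1$features, length_mixture(),
                       small_catalog()$abundance_weights, 200, seed = 5)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
})

test_that("without repeats, long reads map uniquely apart from antisense ambiguity", {
  spec <- genome_spec(n_chromosomes = 1, chromosome_length = 20000,
                      repeat_fraction = 0, seed = 2L)
  gen <- generate_genome(spec, small_catalog())
  expect_identical(nrow(gen$repeats), 0L)
  sim <- simulate_reads(gen$genome, gen$features, length_mixture(),
                        small_catalog()$abundance_weights, 100, seed = 3)
  long <- sim$reads[Biostrings::width(sim$reads) >= 17]
  hits <- oracle_align(long, gen$genome)
  # exactly one genomic locus per read (one row: strand is determined by
  # which of insert / revcomp matches)
  expect_true(all(table(hits$read_id) == 1))
})

test_that("repeat blocks are exact duplications found at exactly two loci", {
  spec <- genome_spec(n_chromosomes = 1, chromosome_length = 20000,
                      repeat_fraction = 0.02, seed = 4L)
  gen <- generate_genome(spec, small_catalog())
  expect_gt(nrow(gen$repeats), 0)
  chrom_str <- as.character(gen$genome)
  for (i in seq_len(min(5, nrow(gen$repeats)))) {
    r <- gen$repeats[i, ]
    block <- substr(chrom_str[[r$src_chrom]], r$src_start,
                    r$src_start + r$length - 1L)
    n_loci <- sum(vapply(names(gen$genome), function(cm) {
      length(Biostrings::matchPattern(block, gen$genome[[cm]]))
    }, integer(1)))
    expect_identical(n_loci, 2L)
  }
})

test_that("degenerate mixtures and weights behave as specified", {
  fix <- tiny_fixture()
  mix10 <- length_mixture(components = data.frame(mode_nt = 10, spread_nt = 0,
                                                  weight = 1),
                          min_nt = 10, max_nt = 10)
  sim <- simulate_reads(fix$genome, fix$features, mix10,
                        c(mRNA = 1), 50, seed = 1)
  expect_true(all(Biostrings::width(sim$reads) == 10))
  expect_true(all(sim$truth$class == "mRNA"))
  expect_true(all(sim$truth$feature_id == "mRNA_A"))
})

test_that("short-length fraction matches the binomial oracle", {
  spec <- genome_spec(n_chromosomes = 1, chromosome_length = 20000,
                      repeat_fraction = 0, seed = 6L)
  gen <- generate_genome(spec, small_catalog())
  mix <- length_mixture(components = data.frame(mode_nt = c(10, 20),
                                                spread_nt = c(0, 0),
                                                weight = c(0.5, 0.5)),
                        min_nt = 10, max_nt = 20)
  sim <- simulate_reads(gen$genome, gen$features, mix,
                        small_catalog()$abundance_weights, 10000, seed = 7)
  p_short <- mean(sim$truth$length <= 12)
  expect_lt(abs(p_short - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("every error-free read's truth locus is recovered by exact search", {
  fix <- tiny_fixture()
  sim <- simulate_reads(fix$genome, fix$features, length_mixture(),
                        c(mRNA = 0.5, antisense = 0.2, CUT = 0.3), 60, seed = 8)
  hits <- oracle_align(sim$reads, fix$genome)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    h <- hits[hits$read_id == tr$read_id, ]
    expect_true(any(h$chrom == tr$chrom & h$start == tr$start &
                      h$strand == tr$strand),
                label = paste("truth locus recovered for", tr$read_id))
  }
})

test_that("source-class proportions converge to the abundance weights", {
  spec <- genome_spec(n_chromosomes = 1, chromosome_length = 25000,
                      repeat_fraction = 0, seed = 9L)
  cat <- small_catalog()
  gen <- generate_genome(spec, cat)
  sim <- simulate_reads(gen$genome, gen$features, length_mixture(),
                        cat$abundance_weights, 10000, seed = 10)
  w <- cat$abundance_weights[names(cat$abundance_weights) %in%
                               unique(S4Vectors::mcols(gen$features)$class)]
  obs <- table(factor(sim$truth$class, levels = names(w)))
  gof <- stats::chisq.test(obs, p = w / sum(w))
  expect_gt(gof$p.value, 0.01)
})

test_that("adapter attachment follows the presence and error models", {
  fix <- tiny_fixture()
  sim <- simulate_reads(fix$genome, fix$features, length_mixture(),
                        c(mRNA = 1), 1000, seed = 11)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"

  all_on <- attach_adapters(sim$reads, adapter, adapter_present_prob = 1,
                            per_base_error_rate = 0, seed = 1)
  expect_true(all(endsWith(as.character(all_on$sequences), adapter)))

  none <- attach_adapters(sim$reads, adapter, adapter_present_prob = 0,
                          per_base_error_rate = 0, seed = 1)
  expect_false(any(none$has_adapter))
  # restrict to reads that genuinely lack adapter-like sequence (a genomic
  # insert can end in adapter-prefix-like bases by chance; any detector must
  # treat those as adapter-bearing), then nothing survives trimming
  bare <- stats::setNames(as.character(none$sequences),
                          names(none$sequences))
  premise_ok <- !oracle_has_adapter(bare, trim_policy(adapter))
  expect_gt(sum(premise_ok), 900)
  pre <- preprocess_reads(bare[premise_ok], trim_policy(adapter))
  expect_identical(unname(pre$tally["retained"]), 0L)

  noisy <- attach_adapters(sim$reads, adapter, adapter_present_prob = 1,
                           per_base_error_rate = 0.1, seed = 2)
  seqs <- as.character(noisy$sequences)
  tails <- substr(seqs, nchar(seqs) - nchar(adapter) + 1L, nchar(seqs))
  a <- strsplit(adapter, "")[[1]]
  mism <- sum(vapply(tails, function(t) sum(strsplit(t, "")[[1]] != a),
                     numeric(1)))
  n_trials <- 1000 * nchar(adapter)
  # substitutions draw a *different* base, so every error is one mismatch
  expect_lt(abs(mism - n_trials * 0.1), 3 * sqrt(n_trials * 0.1 * 0.9))
})
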
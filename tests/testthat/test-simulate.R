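small_params <- function(...) {
  simulation_params(genome_size = 2e4, n_fragments = 2000,
                    frag_len_mean = 120, frag_len_sd = 15, n_sites = 10,
                    read_length = 30, seed = 99, ...)
}

test_that("parameter validation enforces the invariants", {
  expect_error(simulation_params(enrichment_fraction = 1.2),
               class = "masc_usage_error")
  expect_error(simulation_params(frag_len_mean = 20, read_length = 36),
               class = "masc_usage_error")
  expect_error(simulation_params(unmappable_block_mean = 0),
               class = "masc_usage_error")
  expect_error(simulation_params(frag_len_sd = -1),
               class = "masc_usage_error")
})

test_that("simulated mappability hits the target fraction with merged intervals", {
  p <- small_params(unmappable_fraction = 0.25, unmappable_block_mean = 40)
  m <- simulate_mappability(p)
  frac <- 1 - masc:::iv_length(m$intervals$chr1) / 2e4
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.3)
  iv <- m$intervals$chr1
  expect_true(all(diff(iv[, 1]) > 0))
  expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
  # degenerate fractions
  m0 <- simulate_mappability(small_params(unmappable_fraction = 0))
  expect_identical(unname(m0$intervals$chr1[, 1]), 0)
  expect_identical(unname(m0$intervals$chr1[, 2]), 2e4)
  m1 <- simulate_mappability(small_params(unmappable_fraction = 1))
  expect_identical(nrow(m1$intervals$chr1), 0L)
  # determinism
  expect_identical(simulate_mappability(p), simulate_mappability(p))
})

test_that("fully mappable + no PCR duplicates: one read per fragment", {
  p <- small_params()
  sim <- simulate_experiment(p)
  expect_equal(nrow(sim$reads$reads), p$n_fragments)
  expect_equal(nrow(sim$fragments$fragments), p$n_fragments)
  expect_true(all(sim$reads$reads$end - sim$reads$reads$start ==
                    p$read_length))
  # + reads start at their fragment start; - reads end at the fragment end
  r <- sim$reads$reads
  f <- sim$fragments$fragments
  expect_true(all(r$start[r$strand == "+"] == f$start[r$strand == "+"]))
  expect_true(all(r$end[r$strand == "-"] == f$end[r$strand == "-"]))
  expect_identical(simulate_experiment(p)$reads$reads, r)  # deterministic
})

test_that("fragment lengths follow the configured truncated normal", {
  p <- simulation_params(genome_size = 1e5, n_fragments = 20000, seed = 3)
  sim <- simulate_experiment(p)
  truth <- true_mean_fragment_length(sim$fragments)
  expect_lt(abs(truth - p$frag_len_mean),
            3 * p$frag_len_sd / sqrt(p$n_fragments))
  len <- sim$fragments$fragments$end - sim$fragments$fragments$start
  expect_true(all(len >= p$read_length))
})

test_that("retention rule: alignment starts of kept reads are mappable", {
  p <- small_params(unmappable_fraction = 0.3, unmappable_block_mean = 40)
  map <- simulate_mappability(p)
  sim <- simulate_experiment(p, map)
  r <- sim$reads$reads
  expect_lt(nrow(r), p$n_fragments)  # something was discarded
  plus <- r$strand == "+"
  expect_true(all(masc:::iv_contains(map$intervals$chr1, r$start[plus])))
  expect_true(all(masc:::iv_contains(map$intervals$chr1,
                                     r$end[!plus] - p$read_length)))
  # ground truth holds exactly the fragments whose reads were retained
  expect_identical(nrow(sim$fragments$fragments), nrow(r))
})

test_that("PCR duplicates re-emit retained reads", {
  p <- small_params(pcr_duplicate_rate = 0.2)
  sim <- simulate_experiment(p)
  n <- nrow(sim$reads$reads)
  expect_gt(n, p$n_fragments * 1.1)
  expect_lt(n, p$n_fragments * 1.3)
  dup <- grepl("_dup$", sim$reads$reads$name)
  orig <- sim$reads$reads[!dup, c("chrom", "start", "strand")]
  dups <- sim$reads$reads[dup, c("chrom", "start", "strand")]
  expect_true(all(do.call(paste, dups) %in% do.call(paste, orig)))
})

test_that("true_mean_fragment_length is the arithmetic mean", {
  pf <- structure(list(fragments = data.frame(
    chrom = "chr1", start = c(0, 100), end = c(150, 260))),
    class = "PairedFragmentSet")
  expect_identical(true_mean_fragment_length(pf), 155)
  pf1 <- structure(list(fragments = data.frame(
    chrom = "chr1", start = 10, end = 164)), class = "PairedFragmentSet")
  expect_identical(true_mean_fragment_length(pf1), 154)
  empty <- structure(list(fragments = data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0))),
    class = "PairedFragmentSet")
  expect_error(true_mean_fragment_length(empty), class = "masc_data_error")
})

test_that("multi-chromosome simulation spreads sites and reads", {
  p <- simulation_params(genome_size = 6e4, n_chromosomes = 3,
                         n_fragments = 3000, seed = 17)
  sim <- simulate_experiment(p)
  expect_identical(sort(unique(sim$reads$reads$chrom)),
                   c("chr1", "chr2", "chr3"))
  sizes <- masc:::sim_chrom_sizes(p)
  expect_identical(unname(sizes), rep(2e4, 3))
  pr <- reads_to_profiles(sim$reads, sizes)
  expect_identical(length(pr$chroms), 3L)
})
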
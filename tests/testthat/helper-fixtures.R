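# Fixtures built in code: toy instances, random instances for the
# equivalence properties, and comparison helpers.

# the 12-bp toy: M = {[0,3), [6,9)}, R = 3, + origins {1, 7}, - {4, 10}
toy_profiles <- function() {
  strand_profiles(list(chr1 = list(pos = c(1, 7), neg = c(4, 10))),
                  c(chr1 = 12), read_length = 3)
}

toy_map <- function() {
  mappability_map(list(chr1 = data.frame(start = c(0, 6), end = c(3, 9))),
                  read_length = 3, chrom_sizes = c(chr1 = 12))
}

# random instance: chrom sizes <= 5 kb, R in 3..10, random mappability and
# reads (reads are not restricted to mappable positions on purpose: MaSC
# must discard them via DM_d)
random_instance <- function(seed, n_chrom = 1) {
  set.seed(seed)
  sizes <- stats::setNames(sample(200:5000, n_chrom, replace = TRUE),
                           paste0("chr", seq_len(n_chrom)))
  R <- sample(3:10, 1)
  origins <- lapply(sizes, function(B) {
    list(pos = sample(0:(B - R), sample(20:200, 1), replace = TRUE),
         neg = sample((R - 1):(B - 1), sample(20:200, 1), replace = TRUE))
  })
  ivs <- lapply(sizes, function(B) {
    n_iv <- sample(3:15, 1)
    s <- sample(0:(B - 2), n_iv, replace = TRUE)
    data.frame(start = s,
               end = pmin(s + sample(1:ceiling(B / 4), n_iv,
                                     replace = TRUE), B))
  })
  list(profiles = strand_profiles(origins, sizes, R),
       map = mappability_map(ivs, read_length = R, chrom_sizes = sizes),
       full_map = full_mappability(sizes, R),
       R = R, sizes = sizes,
       d_max = min(50, min(sizes) - 1))
}

expect_curves_agree <- function(a, b, tol) {
  expect_identical(a$shift, b$shift)
  expect_identical(is.na(a$value), is.na(b$value))
  expect_equal(a$count, b$count, tolerance = 1e-12, ignore_attr = TRUE)
  if (any(!is.na(a$value)))
    expect_lt(max(abs(a$value - b$value), na.rm = TRUE), tol)
}

# shared simulation worlds (computed lazily once per test run)
sim_world <- local({
  cache <- list()
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    params <- switch(name,
      recovery = simulation_params(seed = 1),
      phantom = simulation_params(unmappable_fraction = 0.3,
                                  enrichment_fraction = 0.1, seed = 1))
    map <- simulate_mappability(params)
    sim <- simulate_experiment(params, map)
    w <- list(params = params, map = map, sim = sim,
              truth = true_mean_fragment_length(sim$fragments),
              profiles = reads_to_profiles(
                sim$reads, masc:::sim_chrom_sizes(params)))
    cache[[name]] <<- w
    w
  }
})
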
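# frozen toy values (computed by the brute-force oracle / direct summation)
# B = 12, M = {[0,3),[6,9)}, R = 3, + origins {1,7}, - origins {4,10}

test_that("toy MaSC curve matches oracle-frozen values, both backends", {
  pr <- toy_profiles()
  map <- toy_map()
  want_r <- c(NA, NA, -0.5, 1, NA, NA)
  want_n <- c(2, 4, 6, 4, 2, 0)
  for (be in c("bits", "lists")) {
    cv <- masc_cross_correlation(pr, map, 0, 5, backend = be)
    expect_equal(cv$value, want_r, tolerance = 1e-12)
    expect_equal(cv$count, want_n, ignore_attr = TRUE)
  }
  o <- brute_force_cc_oracle(pr, map, 0, 5, method = "masc")
  expect_equal(o$value, want_r, tolerance = 1e-12)
  expect_equal(o$count, want_n, ignore_attr = TRUE)
})

test_that("toy naive curves match direct-summation values; argmax at d = 3", {
  pr <- toy_profiles()
  # exact Pearson over the overlap window
  want_exact <- c(-1 / 5, -2 / 9, -1 / 4, 1, -1 / 3, -1 / 6)
  # approximate variant: global means/sds, window-normalised numerator
  want_approx <- c(-1 / 5, -13 / 55, -7 / 25, 19 / 15, -2 / 5, -1 / 7)
  ex <- naive_cross_correlation(pr, 0, 5, variant = "exact")
  ap <- naive_cross_correlation(pr, 0, 5, variant = "approx")
  expect_equal(ex$value, want_exact, tolerance = 1e-12)
  expect_equal(ap$value, want_approx, tolerance = 1e-12)
  expect_equal(ex$count, 12 - (0:5), ignore_attr = TRUE)
  o <- brute_force_cc_oracle(pr, NULL, 0, 5, method = "naive-exact")
  expect_equal(o$value, want_exact, tolerance = 1e-12)
  expect_identical(estimate_fragment_length(ex)$estimate, 3)
  expect_identical(estimate_fragment_length(ap)$estimate, 3)
})

test_that("identical binary profiles give r(0) = 1 (exact variant)", {
  pr <- strand_profiles(list(chr1 = list(pos = c(3, 9, 17),
                                         neg = c(3, 9, 17))),
                        c(chr1 = 30), read_length = 4)
  cv <- naive_cross_correlation(pr, 0, 5, variant = "exact")
  expect_equal(cv$value[1], 1, tolerance = 1e-12)
})

test_that("a strand with no reads yields an undefined, flagged curve", {
  pr <- strand_profiles(list(chr1 = list(pos = c(3, 9), neg = numeric(0))),
                        c(chr1 = 30), read_length = 4)
  for (variant in c("approx", "exact")) {
    cv <- naive_cross_correlation(pr, 0, 5, variant = variant)
    expect_true(all(is.na(cv$value)))
    expect_true(cv$zero_variance)
  }
  cv <- masc_cross_correlation(pr, full_mappability(c(chr1 = 30), 4), 0, 5)
  expect_true(all(is.na(cv$value)))
  expect_true(cv$zero_variance)
})

test_that("shift range is validated against chromosome sizes", {
  pr <- toy_profiles()
  expect_error(naive_cross_correlation(pr, 0, 12), "d_max",
               class = "masc_data_error")
  expect_error(naive_cross_correlation(pr, -1, 5), "d_min",
               class = "masc_usage_error")
})

test_that("map/profile read-length mismatch is an error; unknown R warns", {
  pr <- toy_profiles()
  map <- toy_map()
  map$read_length <- 5
  expect_error(masc_cross_correlation(pr, map, 0, 5), "read length",
               class = "masc_data_error")
  map$read_length <- NA_real_
  expect_warning(masc_cross_correlation(pr, map, 0, 5), "unknown")
})

test_that("backend equivalence: lists == bits == oracle on random instances", {
  for (i in 1:12) {
    inst <- random_instance(i)
    for (method in c("masc", "naive-exact")) {
      o <- brute_force_cc_oracle(inst$profiles, inst$map, 0, inst$d_max,
                                 method = method)
      if (method == "masc") {
        a <- masc_cross_correlation(inst$profiles, inst$map, 0, inst$d_max,
                                    backend = "lists")
        b <- masc_cross_correlation(inst$profiles, inst$map, 0, inst$d_max,
                                    backend = "bits")
      } else {
        a <- naive_cross_correlation(inst$profiles, 0, inst$d_max,
                                     variant = "exact", backend = "lists")
        b <- naive_cross_correlation(inst$profiles, 0, inst$d_max,
                                     variant = "exact", backend = "bits")
      }
      expect_curves_agree(a, o, 1e-9)
      expect_curves_agree(b, o, 1e-9)
      expect_curves_agree(a, b, 1e-12)
    }
  }
})

test_that("whole-genome pooling matches the oracle's pooled Pearson", {
  for (i in 1:4) {
    inst <- random_instance(i + 100, n_chrom = 3)
    o <- brute_force_cc_oracle(inst$profiles, inst$map, 0, inst$d_max,
                               method = "masc", scope = "whole-genome")
    cv <- masc_cross_correlation(inst$profiles, inst$map, 0, inst$d_max)
    expect_curves_agree(cv, o, 1e-9)
    # per-chromosome scope returns one curve per chromosome matching
    # single-chromosome oracles
    bc <- masc_cross_correlation(inst$profiles, inst$map, 0, inst$d_max,
                                 scope = "chromosome")
    ob <- brute_force_cc_oracle(inst$profiles, inst$map, 0, inst$d_max,
                                method = "masc", scope = "chromosome")
    expect_identical(names(bc), names(inst$profiles$chroms))
    for (ch in names(bc)) expect_curves_agree(bc[[ch]], ob[[ch]], 1e-9)
  }
})

test_that("defined exact/MaSC correlations stay in [-1, 1]", {
  for (i in 1:10) {
    inst <- random_instance(i + 200)
    for (cv in list(
      masc_cross_correlation(inst$profiles, inst$map, 0, inst$d_max),
      naive_cross_correlation(inst$profiles, 0, inst$d_max,
                              variant = "exact"))) {
      v <- cv$value[!is.na(cv$value)]
      expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
    }
  }
})

test_that("non-collapsed profiles use the general variance path (lists backend)", {
  origins <- list(chr1 = list(pos = c(2, 2, 5, 9), neg = c(6, 6, 6, 11)))
  pr <- strand_profiles(origins, c(chr1 = 20), 3, collapse = FALSE)
  cv <- masc_cross_correlation(pr, full_mappability(c(chr1 = 20), 3), 0, 8,
                               backend = "lists")
  # independent dense computation with multiplicities
  f <- numeric(20); f[c(3, 6, 10)] <- c(2, 1, 1)
  g <- numeric(20); g[c(7, 12)] <- c(3, 1)
  for (j in seq_along(cv$shift)) {
    d <- cv$shift[j]
    b <- (3 - 1 - d):(20 - 1 - d)   # DM_d of the full map, 0-based
    b <- b[b >= 0]
    want <- suppressWarnings(stats::cor(f[b + 1], g[b + d + 1]))
    if (is.na(want)) expect_true(is.na(cv$value[j]))
    else expect_equal(cv$value[j], want, tolerance = 1e-12)
  }
  expect_error(
    masc_cross_correlation(pr, full_mappability(c(chr1 = 20), 3), 0, 8,
                           backend = "bits"),
    "binary", class = "masc_data_error")
})
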
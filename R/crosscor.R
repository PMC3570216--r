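# Strand cross-correlation: naive (approximate and exact Pearson variants)
# and mappability-sensitive (MaSC), each computable per chromosome or pooled
# genome-wide, through a list-based or a bit-vector backend.
#
# Both backends reduce each chromosome and shift d to the same sufficient
# statistics: n (positions entering the computation), sf = sum f(b),
# sg = sum g(b+d), sfg = sum f(b) g(b+d), plus sf2/sg2 for non-collapsed
# profiles. Correlations are formed from these afterwards, which is also
# what makes whole-genome pooling a plain sum over chromosomes.

.make_curve <- function(shift, value, count, method, scope,
                        smoothed = FALSE, half_width = NA_integer_,
                        zero_variance = FALSE) {
  structure(list(shift = as.numeric(shift), value = as.numeric(value),
                 count = as.numeric(count), method = method, scope = scope,
                 smoothed = smoothed, half_width = half_width,
                 zero_variance = zero_variance),
            class = "CCCurve")
}

#' @export
print.CCCurve <- function(x, ...) {
  cat(sprintf("CCCurve [%s, %s%s]: shifts %g..%g, %d defined value(s)%s\n",
              x$method, x$scope,
              if (isTRUE(x$smoothed)) ", smoothed" else "",
              min(x$shift), max(x$shift), sum(!is.na(x$value)),
              if (isTRUE(x$zero_variance)) " [zero-variance profile]" else ""))
  invisible(x)
}

#' @export
as.data.frame.CCCurve <- function(x, ...) {
  data.frame(shift = x$shift, n = x$count, r = x$value)
}

# dense logical strand/mask vectors for one chromosome (bit backend)
.dense_inputs <- function(ch, B, R, m_iv, naive) {
  f <- logical(B)
  f[ch$pos$pos + 1] <- TRUE
  g <- logical(B)
  g[ch$neg$pos + 1] <- TRUE
  if (naive) {
    m <- rep(TRUE, B)
    mg <- m
  } else {
    m <- iv_to_logical(m_iv, B)
    mg <- logical(B)
    if (R <= B) mg[R:B] <- m[1:(B - R + 1)]  # negative-strand mappability
  }
  list(f = f, g = g, m = m, mg = mg)
}

# per-chromosome sufficient statistics for shifts d_min..d_max.
# map = NULL selects the naive windows (all positions, no mask).
.cc_stats_by_chrom <- function(profiles, map, d_min, d_max, backend) {
  R <- profiles$read_length
  lapply(names(profiles$chroms), function(chname) {
    ch <- profiles$chroms[[chname]]
    B <- profiles$chrom_sizes[[chname]]
    naive <- is.null(map)
    m_iv <- if (naive) NULL else map$intervals[[chname]]
    if (!naive && is.null(m_iv)) m_iv <- iv_empty()
    D <- d_max - d_min + 1
    if (backend == "bits") {
      if (!profiles$collapsed)
        data_error("bit backend requires collapsed (binary) profiles")
      dv <- .dense_inputs(ch, B, R, m_iv, naive)
      s <- .cc_bit_stats(dv$f, dv$g, dv$m, dv$mg, as.integer(d_min),
                         as.integer(d_max))
      stats <- cbind(s, sf2 = s[, "sf"], sg2 = s[, "sg"])
    } else {
      stats <- matrix(0, nrow = D, ncol = 6,
                      dimnames = list(NULL,
                                      c("n", "sf", "sg", "sfg", "sf2", "sg2")))
      pp <- ch$pos$pos; pc <- ch$pos$count
      np <- ch$neg$pos; nc <- ch$neg$count
      for (j in seq_len(D)) {
        d <- d_min + j - 1
        if (d >= B) next
        dm <- if (naive) iv_matrix(0, B - d)
              else iv_clip(iv_intersect(m_iv, iv_shift(m_iv, R - 1 - d)),
                           0, B - d)
        if (iv_is_empty(dm)) next
        inp <- iv_contains(dm, pp)
        ing <- iv_contains(dm, np - d)
        mi <- match(pp, np - d)
        sel <- !is.na(mi) & inp
        stats[j, ] <- c(iv_length(dm), sum(pc[inp]), sum(nc[ing]),
                        sum(pc[sel] * nc[mi[sel]]),
                        sum(pc[inp]^2), sum(nc[ing]^2))
      }
    }
    list(stats = stats, B = B,
         Nf = sum(ch$pos$count), Ng = sum(ch$neg$count),
         Nf2 = sum(ch$pos$count^2), Ng2 = sum(ch$neg$count^2))
  }) -> out
  names(out) <- names(profiles$chroms)
  out
}

# correlation from pooled per-shift statistics (exact Pearson over the
# participating positions; for binary profiles variance = mu (1 - mu))
.r_exact <- function(st) {
  n <- st[, "n"]
  mu_f <- ifelse(n > 0, st[, "sf"] / n, NA_real_)
  mu_g <- ifelse(n > 0, st[, "sg"] / n, NA_real_)
  vf <- st[, "sf2"] / n - mu_f^2
  vg <- st[, "sg2"] / n - mu_g^2
  ok <- !is.na(mu_f) & vf > 0 & vg > 0
  r <- rep(NA_real_, length(n))
  r[ok] <- ((st[ok, "sfg"] / n[ok]) - mu_f[ok] * mu_g[ok]) /
    sqrt(vf[ok] * vg[ok])
  r
}

# the approximate naive correlation: global (per scope) means and variances
# over all positions, numerator over the overlap window, normalised by the
# window length
.r_approx <- function(stat_list, shifts) {
  Btot <- sum(vapply(stat_list, `[[`, numeric(1), "B"))
  Nf <- sum(vapply(stat_list, `[[`, numeric(1), "Nf"))
  Ng <- sum(vapply(stat_list, `[[`, numeric(1), "Ng"))
  Nf2 <- sum(vapply(stat_list, `[[`, numeric(1), "Nf2"))
  Ng2 <- sum(vapply(stat_list, `[[`, numeric(1), "Ng2"))
  mu_f <- Nf / Btot
  mu_g <- Ng / Btot
  vf <- Nf2 / Btot - mu_f^2
  vg <- Ng2 / Btot - mu_g^2
  num <- rep(0, length(shifts))
  win <- rep(0, length(shifts))
  for (sc in stat_list) {
    w <- pmax(sc$B - shifts, 0)
    num <- num + sc$stats[, "sfg"] - mu_g * sc$stats[, "sf"] -
      mu_f * sc$stats[, "sg"] + w * mu_f * mu_g
    win <- win + w
  }
  ifelse(win > 0 & vf > 0 & vg > 0,
         num / (win * sqrt(vf * vg)), NA_real_)
}

.pool_stats <- function(stat_list) {
  Reduce(`+`, lapply(stat_list, `[[`, "stats"))
}

.check_shift_range <- function(profiles, d_min, d_max) {
  if (d_min < 0) usage_error("d_min must be >= 0")
  if (d_max < d_min) usage_error("d_max must be >= d_min")
  if (d_max >= max(profiles$chrom_sizes))
    data_error(sprintf("d_max (%g) must be below the largest chromosome size (%g)",
                       d_max, max(profiles$chrom_sizes)))
}

.curve_or_list <- function(stat_list, shifts, method, scope, variant,
                           profiles) {
  zero_var <- function(sl) {
    sum(vapply(sl, `[[`, numeric(1), "Nf")) == 0 ||
      sum(vapply(sl, `[[`, numeric(1), "Ng")) == 0
  }
  if (scope == "whole-genome") {
    pooled <- .pool_stats(stat_list)
    v <- if (identical(variant, "approx")) .r_approx(stat_list, shifts)
         else .r_exact(pooled)
    .make_curve(shifts, v, pooled[, "n"], method, "whole-genome",
                zero_variance = zero_var(stat_list))
  } else {
    out <- lapply(names(stat_list), function(chname) {
      sl <- stat_list[chname]
      v <- if (identical(variant, "approx")) .r_approx(sl, shifts)
           else .r_exact(sl[[1L]]$stats)
      .make_curve(shifts, v, sl[[1L]]$stats[, "n"], method, chname,
                  zero_variance = zero_var(sl))
    })
    names(out) <- names(stat_list)
    out
  }
}

#' Naive strand cross-correlation curve
#'
#' Pearson-style correlation between the positive-strand origin profile
#' `f(b)` and the shifted negative-strand profile `g(b + d)` as a function
#' of the shift `d`, ignoring mappability. The `approx` variant uses the
#' global per-scope sample means and variances of `f` and `g` with the
#' covariance summed over the overlap window and divided by the window
#' length; the `exact` variant recomputes means and variances per shift
#' over the overlapped vectors (textbook Pearson).
#'
#' @param profiles A `StrandProfiles` object.
#' @param d_min,d_max Shift range in bp (default 0..500).
#' @param variant `"approx"` (default) or `"exact"`.
#' @param scope `"whole-genome"` (per-shift statistics pooled across
#'   chromosomes, default) or `"chromosome"` (one curve per chromosome).
#' @param backend `"bits"` (packed bit vectors, default) or `"lists"`
#'   (sorted interval/position lists).
#' @return A `CCCurve`, or a named list of them when
#'   `scope = "chromosome"`.
#' @export
naive_cross_correlation <- function(profiles, d_min = 0, d_max = 500,
                                    variant = c("approx", "exact"),
                                    scope = c("whole-genome", "chromosome"),
                                    backend = c("bits", "lists")) {
  stopifnot(inherits(profiles, "StrandProfiles"))
  variant <- match.arg(variant)
  scope <- match.arg(scope)
  backend <- match.arg(backend)
  .check_shift_range(profiles, d_min, d_max)
  shifts <- seq(d_min, d_max)
  sl <- .cc_stats_by_chrom(profiles, NULL, d_min, d_max, backend)
  .curve_or_list(sl, shifts, paste0("naive-", variant), scope, variant,
                 profiles)
}

#' Mappability-sensitive cross-correlation (MaSC) curve
#'
#' Strand cross-correlation evaluated, at each shift `d`, only over the
#' doubly-mappable positions `DM_d` (see [doubly_mappable()]): per-shift
#' means and variances are taken over `DM_d`, and reads outside it are
#' excluded from that shift's computation entirely. This removes the
#' phantom peak at the read length that unmappable regions induce in the
#' naive curve.
#'
#' @inheritParams naive_cross_correlation
#' @param map A `MappabilityMap` whose `read_length` matches the profiles'.
#' @return A `CCCurve`, or a named list of them when
#'   `scope = "chromosome"`.
#' @export
masc_cross_correlation <- function(profiles, map, d_min = 0, d_max = 500,
                                   backend = c("bits", "lists"),
                                   scope = c("whole-genome", "chromosome")) {
  stopifnot(inherits(profiles, "StrandProfiles"),
            inherits(map, "MappabilityMap"))
  backend <- match.arg(backend)
  scope <- match.arg(scope)
  .check_shift_range(profiles, d_min, d_max)
  if (is.na(map$read_length)) {
    warning("mappability map has unknown read length; assuming it matches the profiles",
            call. = FALSE)
    map$read_length <- profiles$read_length
  }
  if (map$read_length != profiles$read_length)
    data_error(sprintf("map read length (%g) != profiles read length (%g)",
                       map$read_length, profiles$read_length))
  missing_ch <- setdiff(names(profiles$chroms), names(map$intervals))
  if (length(missing_ch))
    data_error(sprintf("mappability map lacks chromosome '%s'",
                       missing_ch[1L]))
  shifts <- seq(d_min, d_max)
  sl <- .cc_stats_by_chrom(profiles, map, d_min, d_max, backend)
  .curve_or_list(sl, shifts, "masc", scope, "exact", profiles)
}

#' Moving-average smoothing of a correlation curve
#'
#' Central moving average over `[i - half_width, i + half_width]`, with the
#' window truncated (shrunk) at the curve ends. Undefined input values are
#' excluded from neighbouring windows and remain undefined in the output at
#' their own positions.
#'
#' @param curve A `CCCurve`.
#' @param half_width Number of samples taken on either side (default 15).
#' @return A smoothed `CCCurve` on the same shift grid.
#' @export
smooth_curve <- function(curve, half_width = 15) {
  stopifnot(inherits(curve, "CCCurve"))
  if (half_width < 0) usage_error("half_width must be >= 0")
  v <- curve$value
  n <- length(v)
  if (all(is.na(v))) data_error("curve has no defined values to smooth")
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    w <- v[max(1L, i - half_width):min(n, i + half_width)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  .make_curve(curve$shift, out, curve$count, curve$method, curve$scope,
              smoothed = TRUE, half_width = as.integer(half_width),
              zero_variance = curve$zero_variance)
}

#' Estimate mean fragment length from a correlation curve
#'
#' Returns the smallest shift attaining the maximum defined correlation in
#' `[d_min, d_max]`. Estimates below `failure_threshold` (typically set
#' slightly above the read length) are classified as failures: they sit at
#' or near the phantom peak rather than a plausible fragment length.
#'
#' @param curve A `CCCurve` (raw or smoothed).
#' @param d_min,d_max Search range; defaults to the curve's full grid.
#' @param failure_threshold Optional failure classification threshold in bp.
#' @return A `FragmentLengthEstimate`: list with `estimate`, `d_min`,
#'   `d_max`, `smoothed`, `peak_value`, `is_failure`, `failure_threshold`.
#' @export
estimate_fragment_length <- function(curve, d_min = NULL, d_max = NULL,
                                     failure_threshold = NULL) {
  stopifnot(inherits(curve, "CCCurve"))
  if (is.null(d_min)) d_min <- min(curve$shift)
  if (is.null(d_max)) d_max <- max(curve$shift)
  sel <- curve$shift >= d_min & curve$shift <= d_max
  if (!any(sel)) usage_error("search range contains no shifts")
  v <- curve$value[sel]
  s <- curve$shift[sel]
  if (all(is.na(v)))
    data_error("curve is undefined everywhere in the search range")
  i <- which.max(v)  # NA-ignoring; first (smallest shift) maximum wins
  structure(list(estimate = s[i], d_min = d_min, d_max = d_max,
                 smoothed = isTRUE(curve$smoothed), peak_value = v[i],
                 is_failure = if (is.null(failure_threshold)) NA
                              else s[i] < failure_threshold,
                 failure_threshold = failure_threshold %||% NA_real_,
                 method = curve$method, scope = curve$scope),
            class = "FragmentLengthEstimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.FragmentLengthEstimate <- function(x, ...) {
  cat(sprintf(
    "Fragment length estimate: %g bp [%s, %s%s, range %g..%g, peak r = %.4g%s]\n",
    x$estimate, x$method, x$scope,
    if (x$smoothed) ", smoothed" else "", x$d_min, x$d_max, x$peak_value,
    if (isTRUE(x$is_failure)) ", FAILURE (below threshold)" else ""))
  invisible(x)
}

#' Summarise per-chromosome fragment-length estimates
#'
#' Reports the mean of the chromosomal estimates with 2 standard errors
#' (`2 * s / sqrt(n)`, sample standard deviation) and the percentage of
#' estimates classified as failures (below `failure_threshold`). All
#' estimates, including failures, enter the mean; a failure-excluded mean
#' is reported alongside.
#'
#' @param estimates Named list of `FragmentLengthEstimate` objects, or a
#'   (named) numeric vector of estimates.
#' @param failure_threshold Failure classification threshold in bp.
#' @return A `ChromSummary`: list with `estimates`, `mean`, `two_se`,
#'   `percent_failures`, `n`, `single_observation`,
#'   `mean_excluding_failures`.
#' @export
aggregate_by_chromosome <- function(estimates, failure_threshold) {
  if (is.list(estimates))
    estimates <- vapply(estimates, function(e) e$estimate, numeric(1))
  if (length(estimates) == 0L)
    usage_error("no chromosomal estimates to aggregate")
  n <- length(estimates)
  fail <- estimates < failure_threshold
  structure(list(
    estimates = estimates,
    mean = mean(estimates),
    two_se = if (n > 1) 2 * stats::sd(estimates) / sqrt(n) else 0,
    percent_failures = 100 * mean(fail),
    n = n,
    single_observation = n == 1L,
    mean_excluding_failures = if (any(!fail)) mean(estimates[!fail])
                              else NA_real_,
    failure_threshold = failure_threshold
  ), class = "ChromSummary")
}

#' @export
print.ChromSummary <- function(x, ...) {
  cat(sprintf("Chromosomal estimates (n = %d): mean %.1f +/- %.2f (2SE), %.1f%% failures (< %g bp)\n",
              x$n, x$mean, x$two_se, x$percent_failures,
              x$failure_threshold))
  if (x$single_observation) cat("  (single observation; 2SE reported as 0)\n")
  invisible(x)
}
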
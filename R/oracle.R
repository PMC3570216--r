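# Reference implementation by explicit per-position enumeration. Shares no
# interval or bit-shift code with the production backends; used as the
# independent route in equivalence tests.

#' Brute-force cross-correlation oracle
#'
#' Computes the naive-exact or MaSC correlation by enumerating every genome
#' position at every shift with dense vectors and [stats::cor()], with no
#' interval arithmetic or bit tricks. Intended purely as a test oracle;
#' refuses genomes larger than 1e5 bp.
#'
#' @param profiles A `StrandProfiles` object.
#' @param map A `MappabilityMap`, or `NULL` for the naive correlation.
#' @param d_min,d_max Shift range.
#' @param method `"masc"` or `"naive-exact"`.
#' @param scope `"whole-genome"` or `"chromosome"`.
#' @return A `CCCurve`, or a named list of them when
#'   `scope = "chromosome"`.
#' @export
brute_force_cc_oracle <- function(profiles, map = NULL, d_min = 0,
                                  d_max = 50,
                                  method = c("masc", "naive-exact"),
                                  scope = c("whole-genome", "chromosome")) {
  stopifnot(inherits(profiles, "StrandProfiles"))
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (sum(profiles$chrom_sizes) > 1e5)
    stop("oracle refuses genomes larger than 1e5 bp")
  if (method == "masc" && is.null(map))
    stop("masc oracle needs a mappability map")
  R <- profiles$read_length
  shifts <- seq(d_min, d_max)

  # dense per-chromosome vectors, built by direct position filling
  dense <- lapply(names(profiles$chroms), function(chname) {
    ch <- profiles$chroms[[chname]]
    B <- as.integer(profiles$chrom_sizes[[chname]])
    f <- numeric(B)
    for (k in seq_along(ch$pos$pos))
      f[ch$pos$pos[k] + 1] <- f[ch$pos$pos[k] + 1] + ch$pos$count[k]
    g <- numeric(B)
    for (k in seq_along(ch$neg$pos))
      g[ch$neg$pos[k] + 1] <- g[ch$neg$pos[k] + 1] + ch$neg$count[k]
    m <- rep(TRUE, B)
    if (!is.null(map)) {
      m <- rep(FALSE, B)
      iv <- map$intervals[[chname]]
      if (!is.null(iv) && nrow(iv) > 0)
        for (k in seq_len(nrow(iv))) {
          lo <- iv[k, 1L] + 1
          hi <- min(iv[k, 2L], B)
          if (hi >= lo) m[lo:hi] <- TRUE
        }
    }
    list(f = f, g = g, m = m, B = B)
  })
  names(dense) <- names(profiles$chroms)

  # per shift, collect the (f, g) value pairs entering the computation
  pairs_at <- function(dv, d) {
    B <- dv$B
    if (d >= B) return(list(x = numeric(0), y = numeric(0)))
    b <- 0:(B - 1 - d)
    if (method == "masc") {
      b2 <- b + d - R + 1  # positive-strand start of the shifted - read
      sel <- dv$m[b + 1] & b2 >= 0 & b2 < B
      sel[sel] <- dv$m[b2[sel] + 1]
    } else {
      sel <- rep(TRUE, length(b))
    }
    list(x = dv$f[b[sel] + 1], y = dv$g[b[sel] + d + 1])
  }

  curve_from <- function(chnames, scope_label) {
    vals <- counts <- numeric(length(shifts))
    for (j in seq_along(shifts)) {
      xs <- ys <- numeric(0)
      for (chname in chnames) {
        p <- pairs_at(dense[[chname]], shifts[j])
        xs <- c(xs, p$x)
        ys <- c(ys, p$y)
      }
      counts[j] <- length(xs)
      vals[j] <- if (length(xs) < 2) NA_real_
                 else suppressWarnings(stats::cor(xs, ys))
    }
    zero_var <- sum(unlist(lapply(dense[chnames], `[[`, "f"))) == 0 ||
      sum(unlist(lapply(dense[chnames], `[[`, "g"))) == 0
    .make_curve(shifts, vals, counts, paste0("oracle-", method),
                scope_label, zero_variance = zero_var)
  }

  if (scope == "whole-genome") {
    curve_from(names(dense), "whole-genome")
  } else {
    out <- lapply(names(dense), function(ch) curve_from(ch, ch))
    names(out) <- names(dense)
    out
  }
}
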
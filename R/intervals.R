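# Integer interval primitives, 0-based half-open [start, end).
#
# Interval sets are integer matrices with columns "start" and "end", kept
# sorted, disjoint and non-adjacent (i.e. fully merged). These back both the
# mappability map and the per-shift doubly-mappable sets of the list-based
# backend, where sorted-list intersection is the core algorithmic step.

iv_matrix <- function(start = integer(0), end = integer(0)) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  storage.mode(m) <- "double"   # doubles hold exact integers beyond 2^31
  m
}

iv_empty <- function() iv_matrix()

iv_is_empty <- function(iv) is.null(iv) || nrow(iv) == 0L

# total number of integer positions covered
iv_length <- function(iv) if (iv_is_empty(iv)) 0 else sum(iv[, 2L] - iv[, 1L])

# sort + merge overlapping or adjacent intervals; returns list(iv, n_merged)
# n_merged counts input intervals absorbed into a neighbour.
iv_merge <- function(iv) {
  if (iv_is_empty(iv)) return(list(iv = iv_empty(), n_merged = 0L))
  o <- order(iv[, 1L], iv[, 2L])
  s <- iv[o, 1L]
  e <- iv[o, 2L]
  n <- length(s)
  if (n == 1L) return(list(iv = iv_matrix(s, e), n_merged = 0L))
  # running maximum of ends; a new group starts when start > max(end so far)
  emax <- cummax(e)
  new_grp <- c(TRUE, s[-1L] > emax[-n])
  grp <- cumsum(new_grp)
  gs <- s[new_grp]
  ge <- vapply(split(e, grp), max, numeric(1))
  list(iv = iv_matrix(gs, unname(ge)), n_merged = n - length(gs))
}

# shift all intervals by k base pairs (k may be negative)
iv_shift <- function(iv, k) {
  if (iv_is_empty(iv)) return(iv_empty())
  iv_matrix(iv[, 1L] + k, iv[, 2L] + k)
}

# clip to [lo, hi)
iv_clip <- function(iv, lo, hi) {
  if (iv_is_empty(iv) || lo >= hi) return(iv_empty())
  s <- pmax(iv[, 1L], lo)
  e <- pmin(iv[, 2L], hi)
  keep <- e > s
  iv_matrix(s[keep], e[keep])
}

# intersection of two merged interval sets, via a vectorised coverage sweep:
# positions covered by both sets are exactly those with running coverage 2.
iv_intersect <- function(a, b) {
  if (iv_is_empty(a) || iv_is_empty(b)) return(iv_empty())
  pts <- c(a[, 1L], b[, 1L], a[, 2L], b[, 2L])
  delta <- c(rep(1, nrow(a) + nrow(b)), rep(-1, nrow(a) + nrow(b)))
  o <- order(pts, -delta)  # starts before ends at identical coordinates
  cov <- cumsum(delta[o])
  p <- pts[o]
  open <- which(cov == 2 & delta[o] == 1)
  if (length(open) == 0L) return(iv_empty())
  # each entry into coverage 2 closes at the next event (any -1 drops below 2)
  iv_matrix(p[open], p[open + 1L])
}

# logical membership of integer positions in a merged interval set
iv_contains <- function(iv, pos) {
  if (iv_is_empty(iv)) return(rep(FALSE, length(pos)))
  flat <- as.vector(t(iv))  # strictly increasing: s1 < e1 < s2 < e2 ...
  findInterval(pos, flat) %% 2L == 1L
}

# dense logical occupancy vector of length size (1-based index = position+1)
iv_to_logical <- function(iv, size) {
  v <- logical(size)
  if (!iv_is_empty(iv)) {
    for (i in seq_len(nrow(iv))) {
      s <- iv[i, 1L]
      e <- min(iv[i, 2L], size)
      if (e > s && s < size) v[(s + 1):e] <- TRUE
    }
  }
  v
}
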
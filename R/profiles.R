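# Strand profiles: binary per-chromosome occupancy of read 5'-origins.

#' Low-level StrandProfiles constructor
#'
#' Builds a `StrandProfiles` object directly from origin positions. Mostly
#' useful in tests and simulations; [reads_to_profiles()] is the normal
#' route. Origins are 0-based. Duplicated origins are collapsed (counted in
#' `duplicate_count`) unless `collapse = FALSE`, in which case multiplicity
#' is kept per position.
#'
#' @param origins Named list (per chromosome) of lists with elements `pos`
#'   and `neg`: integer vectors of 5'-origin positions.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param read_length Read length R in bp.
#' @param collapse Collapse duplicate origins to one read (default `TRUE`).
#' @return A `StrandProfiles` object.
#' @export
strand_profiles <- function(origins, chrom_sizes, read_length,
                            collapse = TRUE) {
  stopifnot(is.list(origins), !is.null(names(origins)))
  if (!all(names(origins) %in% names(chrom_sizes)))
    data_error("chrom_sizes missing chromosomes present in origins")
  dup <- 0
  chroms <- lapply(names(origins), function(ch) {
    B <- chrom_sizes[[ch]]
    one_strand <- function(p) {
      p <- as.numeric(p)
      if (length(p) && (min(p) < 0 || max(p) >= B))
        data_error(sprintf("read origin outside [0, %g) on %s", B, ch))
      if (collapse) {
        u <- sort(unique(p))
        dup <<- dup + (length(p) - length(u))
        list(pos = u, count = rep(1, length(u)))
      } else {
        t <- table(p)
        list(pos = as.numeric(names(t)), count = as.numeric(t))
      }
    }
    list(pos = one_strand(origins[[ch]]$pos),
         neg = one_strand(origins[[ch]]$neg))
  })
  names(chroms) <- names(origins)
  structure(list(chroms = chroms,
                 chrom_sizes = chrom_sizes[names(origins)],
                 read_length = as.numeric(read_length),
                 duplicate_count = dup,
                 collapsed = collapse),
            class = "StrandProfiles")
}

#' Convert aligned reads into binary strand profiles
#'
#' Each positive-strand read with interval `[s, e)` contributes its leftmost
#' base `s` as a 5'-origin; each negative-strand read contributes its
#' rightmost base `e - 1` (the physical start of the reverse-complement
#' read). Reads sharing chromosome, strand, and origin are collapsed into a
#' single read (PCR-duplicate removal), so profiles are binary; with this
#' crediting convention the cross-correlation argmax estimates the mean
#' fragment length directly, with no read-length adjustment.
#'
#' @param reads A `ReadSet` from [read_reads_bed()] or
#'   [simulate_experiment()].
#' @param chrom_sizes Named numeric vector covering all chromosomes present.
#' @param collapse Collapse duplicates (default `TRUE`; disabling it keeps
#'   per-position read counts, supported only by the list backend).
#' @return A `StrandProfiles` object.
#' @export
reads_to_profiles <- function(reads, chrom_sizes, collapse = TRUE) {
  stopifnot(inherits(reads, "ReadSet"))
  r <- reads$reads
  unknown <- setdiff(unique(r$chrom), names(chrom_sizes))
  if (length(unknown))
    data_error(sprintf("chromosome '%s' not in chrom_sizes", unknown[1L]))
  origin <- ifelse(r$strand == "+", r$start, r$end - 1)
  bad <- which(origin < 0 | origin >= chrom_sizes[r$chrom])
  if (length(bad))
    data_error(sprintf("read '%s' has origin %g outside [0, %g) on %s",
                       r$name[bad[1L]], origin[bad[1L]],
                       chrom_sizes[[r$chrom[bad[1L]]]], r$chrom[bad[1L]]))
  origins <- lapply(split(data.frame(origin = origin, strand = r$strand),
                          r$chrom), function(d)
    list(pos = d$origin[d$strand == "+"],
         neg = d$origin[d$strand == "-"]))
  strand_profiles(origins, chrom_sizes, reads$read_length,
                  collapse = collapse)
}

#' @export
print.StrandProfiles <- function(x, ...) {
  npos <- sum(vapply(x$chroms, function(c) sum(c$pos$count), numeric(1)))
  nneg <- sum(vapply(x$chroms, function(c) sum(c$neg$count), numeric(1)))
  cat(sprintf(
    "StrandProfiles: %d chromosome(s), R = %g, %g +-origins, %g --origins, %g duplicates removed\n",
    length(x$chroms), x$read_length, npos, nneg, x$duplicate_count))
  invisible(x)
}

#' Doubly-mappable positions at a shift
#'
#' Returns, per chromosome, the set `DM_d` of positions `b` such that `b` is
#' a mappable positive-strand start and `b + d` is a valid 5'-origin for a
#' mappable negative-strand read (i.e. `b + d - R + 1` is a mappable
#' positive-strand start), with both positions inside the chromosome. These
#' are the only positions at which MaSC evaluates the correlation at shift
#' `d`. Computed as the intersection of the map with itself shifted by
#' `R - 1 - d`, clipped to `[0, chrom_size - d)`.
#'
#' @param map A `MappabilityMap` with known `read_length`.
#' @param d Non-negative shift in bp.
#' @return Named list of merged interval matrices (0-based half-open).
#' @export
doubly_mappable <- function(map, d) {
  stopifnot(inherits(map, "MappabilityMap"), d >= 0)
  R <- map$read_length
  if (is.na(R)) data_error("mappability map has unknown read length")
  out <- lapply(names(map$intervals), function(ch) {
    m <- map$intervals[[ch]]
    B <- map$chrom_sizes[[ch]]
    iv_clip(iv_intersect(m, iv_shift(m, R - 1 - d)), 0, B - d)
  })
  names(out) <- names(map$intervals)
  out
}

#' Fully mappable map (every position a unique start)
#'
#' Convenience constructor for a map covering `[0, chrom_size)` on every
#' chromosome; with it, MaSC reduces to the exact naive correlation for all
#' shifts `d >= R - 1`.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param read_length Read length R in bp.
#' @return A `MappabilityMap`.
#' @export
full_mappability <- function(chrom_sizes, read_length) {
  ivs <- lapply(chrom_sizes, function(B) data.frame(start = 0, end = B))
  mappability_map(ivs, read_length = read_length, chrom_sizes = chrom_sizes)
}
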
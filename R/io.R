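# Readers and writers: BED6 reads, BED3/bedGraph mappability, chrom.sizes,
# and the TSV curve table.

.read_data_lines <- function(path) {
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.int_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad))
    data_error(sprintf("line %d: non-integer %s field '%s'",
                       lineno[bad[1L]], what, x[bad[1L]]))
  v
}

#' Read single-end aligned reads from a BED6 file
#'
#' Loads aligned reads from a BED file with at least six columns
#' (chrom, start, end, name, score, strand). Coordinates are 0-based
#' half-open; the strand column must be `+` or `-`.
#'
#' @param path Path to a BED file.
#' @param expected_read_length Optional known read length R in bp. When
#'   omitted, R is inferred as the modal `end - start` over all records.
#' @param tolerate_length_mismatch If `FALSE` (default), any record whose
#'   length differs from the (expected or modal) read length is an error.
#'   If `TRUE`, such records are kept, counted, and reported via a warning.
#' @return A `ReadSet`: list with `reads` (data.frame of chrom, start, end,
#'   name, score, strand), `read_length`, and `length_mismatch_count`.
#' @export
read_reads_bed <- function(path, expected_read_length = NULL,
                           tolerate_length_mismatch = FALSE) {
  dl <- .read_data_lines(path)
  if (length(dl$lines) == 0L) data_error(sprintf("empty BED file: %s", path))
  fields <- .split_fields(dl$lines)
  nf <- lengths(fields)
  if (any(nf < 6L))
    data_error(sprintf(
      "line %d: reads BED requires >= 6 columns (strand in column 6), got %d",
      dl$lineno[which(nf < 6L)[1L]], nf[which(nf < 6L)[1L]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .int_or_stop(vapply(fields, `[[`, "", 2L), "start", dl$lineno)
  end <- .int_or_stop(vapply(fields, `[[`, "", 3L), "end", dl$lineno)
  name <- vapply(fields, `[[`, "", 4L)
  score <- vapply(fields, `[[`, "", 5L)
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- which(start < 0)
  if (length(bad))
    data_error(sprintf("line %d: negative start", dl$lineno[bad[1L]]))
  bad <- which(end <= start)
  if (length(bad))
    data_error(sprintf("line %d: end <= start", dl$lineno[bad[1L]]))
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    data_error(sprintf("line %d: strand must be '+' or '-', got '%s'",
                       dl$lineno[bad[1L]], strand[bad[1L]]))
  len <- end - start
  if (is.null(expected_read_length)) {
    tab <- table(len)
    read_length <- as.numeric(names(tab)[which.max(tab)])
  } else {
    read_length <- as.numeric(expected_read_length)
  }
  mism <- sum(len != read_length)
  if (mism > 0L) {
    if (!tolerate_length_mismatch)
      data_error(sprintf(
        "%d of %d reads have length != %g (set tolerate_length_mismatch = TRUE to keep them)",
        mism, length(len), read_length))
    warning(sprintf("%d reads differ from read length %g; kept", mism,
                    read_length), call. = FALSE)
  }
  structure(list(
    reads = data.frame(chrom = chrom, start = start, end = end,
                       name = name, score = score, strand = strand,
                       stringsAsFactors = FALSE),
    read_length = read_length,
    length_mismatch_count = as.integer(mism)
  ), class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, read length %g bp, %d chromosome(s)",
              nrow(x$reads), x$read_length,
              length(unique(x$reads$chrom))), "\n")
  if (x$length_mismatch_count > 0)
    cat(sprintf("  %d reads with non-modal length\n",
                x$length_mismatch_count))
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file with chromosome name and length in bp.
#' @return Named numeric vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  dl <- .read_data_lines(path)
  fields <- .split_fields(dl$lines)
  if (any(lengths(fields) < 2L))
    data_error("chrom.sizes requires two columns")
  sizes <- .int_or_stop(vapply(fields, `[[`, "", 2L), "size", dl$lineno)
  names(sizes) <- vapply(fields, `[[`, "", 1L)
  sizes
}

#' Construct a mappability map from per-chromosome intervals
#'
#' Low-level constructor; most users should call [read_mappability()] or
#' [simulate_mappability()]. Intervals are 0-based half-open positions that
#' are valid unique positive-strand starts for length-R reads.
#'
#' @param intervals Named list (one entry per chromosome) of two-column
#'   matrices or data.frames with columns start, end.
#' @param read_length Read length R the map was computed for (`NA` if
#'   unknown).
#' @param chrom_sizes Named numeric vector of chromosome lengths; when
#'   `NULL`, inferred as the maximum end coordinate per chromosome and
#'   flagged as such.
#' @return A `MappabilityMap`.
#' @export
mappability_map <- function(intervals, read_length = NA_real_,
                            chrom_sizes = NULL) {
  stopifnot(is.list(intervals), !is.null(names(intervals)))
  merged <- 0L
  ivs <- lapply(intervals, function(x) {
    m <- iv_matrix(x[, 1L], x[, 2L])
    if (any(m[, 2L] <= m[, 1L])) data_error("interval with end <= start")
    if (any(m[, 1L] < 0)) data_error("negative interval start")
    r <- iv_merge(m)
    merged <<- merged + r$n_merged
    r$iv
  })
  inferred <- is.null(chrom_sizes)
  if (inferred) {
    chrom_sizes <- vapply(ivs, function(m)
      if (iv_is_empty(m)) 0 else max(m[, 2L]), numeric(1))
  } else {
    if (!all(names(ivs) %in% names(chrom_sizes)))
      data_error("chrom_sizes missing chromosomes present in mappability")
    over <- vapply(names(ivs), function(ch) {
      m <- ivs[[ch]]
      !iv_is_empty(m) && max(m[, 2L]) > chrom_sizes[[ch]]
    }, logical(1))
    if (any(over))
      data_error(sprintf("mappability intervals exceed chromosome size on %s",
                         names(ivs)[over][1L]))
  }
  structure(list(intervals = ivs,
                 read_length = as.numeric(read_length),
                 chrom_sizes = chrom_sizes,
                 sizes_inferred = inferred,
                 n_merged = merged),
            class = "MappabilityMap")
}

#' Read a mappability map from BED3 or bedGraph
#'
#' BED3 input is taken as intervals of uniquely-mappable positive-strand
#' start positions. bedGraph input carries a uniqueness score in `[0, 1]` in
#' column 4; only intervals with score `>= score_threshold` are kept.
#' Either way, intervals are then sorted and merged.
#'
#' @param path Path to a BED3 or bedGraph file.
#' @param score_threshold Minimum uniqueness score for bedGraph input
#'   (default 1.0: strictly unique positions only).
#' @param read_length Read length R the map corresponds to (optional).
#' @param chrom_sizes Named numeric vector, or path to a chrom.sizes file,
#'   or `NULL` to infer sizes from the maximum coordinate seen (flagged).
#' @return A `MappabilityMap`.
#' @export
read_mappability <- function(path, score_threshold = 1.0,
                             read_length = NA_real_, chrom_sizes = NULL) {
  dl <- .read_data_lines(path)
  if (length(dl$lines) == 0L)
    data_error(sprintf("empty mappability file: %s", path))
  fields <- .split_fields(dl$lines)
  nf <- lengths(fields)
  if (any(nf < 3L))
    data_error(sprintf("line %d: mappability requires >= 3 columns",
                       dl$lineno[which(nf < 3L)[1L]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .int_or_stop(vapply(fields, `[[`, "", 2L), "start", dl$lineno)
  end <- .int_or_stop(vapply(fields, `[[`, "", 3L), "end", dl$lineno)
  if (any(end <= start))
    data_error(sprintf("line %d: end <= start",
                       dl$lineno[which(end <= start)[1L]]))
  is_bedgraph <- all(nf >= 4L)
  if (is_bedgraph) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    if (anyNA(score)) is_bedgraph <- FALSE  # 4th column not numeric: BED
  }
  if (is_bedgraph) {
    if (any(score < 0 | score > 1))
      data_error("bedGraph uniqueness score outside [0, 1]")
    keep <- score >= score_threshold
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  } else if (any(nf != 3L) && !all(nf >= 4L)) {
    data_error("mixed column counts: not BED3 nor bedGraph")
  }
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  ivs <- split(data.frame(start, end), chrom)
  mappability_map(ivs, read_length = read_length, chrom_sizes = chrom_sizes)
}

#' @export
print.MappabilityMap <- function(x, ...) {
  cat(sprintf(
    "MappabilityMap: %d chromosome(s), R = %s, %g of %g bp mappable%s\n",
    length(x$intervals),
    if (is.na(x$read_length)) "unknown" else format(x$read_length),
    sum(vapply(x$intervals, iv_length, numeric(1))),
    sum(x$chrom_sizes),
    if (x$sizes_inferred) " (sizes inferred)" else ""))
  invisible(x)
}

#' Write a raw and a smoothed cross-correlation curve as a TSV table
#'
#' Columns are `shift`, `n` (positions entering the computation at that
#' shift), `r_raw` and `r_smoothed`. Undefined correlations are written as
#' `NA`. Values are printed with 17 significant digits so that reading the
#' table back reproduces them exactly.
#'
#' @param curve,smoothed `CCCurve` objects on identical shift grids.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_curve_table <- function(curve, smoothed, path) {
  stopifnot(inherits(curve, "CCCurve"), inherits(smoothed, "CCCurve"))
  if (!identical(curve$shift, smoothed$shift))
    data_error("raw and smoothed curves have different shift grids")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c("shift\tn\tr_raw\tr_smoothed",
             sprintf("%d\t%s\t%s\t%s", as.integer(curve$shift),
                     sprintf("%.0f", curve$count),
                     fmt(curve$value), fmt(smoothed$value)))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a curve table written by [write_curve_table()]
#'
#' @param path Path to the TSV table.
#' @return data.frame with columns shift, n, r_raw, r_smoothed.
#' @export
read_curve_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    na.strings = "NA", colClasses = "numeric")
}

# --- writers used by the simulator / CLI ------------------------------------

#' Write a ReadSet as BED6
#' @param reads A `ReadSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  r <- reads$reads
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s", r$chrom, r$start, r$end,
                     r$name, r$score, r$strand), path)
  invisible(path)
}

#' Write a MappabilityMap as BED3
#' @param map A `MappabilityMap`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mappability_bed <- function(map, path) {
  lines <- unlist(lapply(names(map$intervals), function(ch) {
    m <- map$intervals[[ch]]
    if (iv_is_empty(m)) return(character(0))
    sprintf("%s\t%.0f\t%.0f", ch, m[, 1L], m[, 2L])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a PairedFragmentSet as BED3
#' @param pairs A `PairedFragmentSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments_bed <- function(pairs, path) {
  f <- pairs$fragments
  writeLines(sprintf("%s\t%.0f\t%.0f", f$chrom, f$start, f$end), path)
  invisible(path)
}
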
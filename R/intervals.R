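# Peak-file I/O and interval algebra. Coordinates are 0-based half-open in
# every file read or written and in make_intervals(); internally intervals
# live in GRanges (1-based closed), converted only at the boundary.

#' Build a GRanges from 0-based half-open coordinates
#'
#' Constructor for genomic intervals in the BED convention used throughout
#' the package: `start` is 0-based inclusive, `end` exclusive. Zero- or
#' negative-length intervals are rejected.
#'
#' @param chrom character vector of chromosome names (no whitespace).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param score optional non-negative numeric (e.g. signal or -log10 q).
#' @param name optional character identifiers.
#' @return A sorted `GRanges`.
#' @examples
#' make_intervals("chr1", 100, 200)
#' @export
make_intervals <- function(chrom, start, end, score = NULL, name = NULL) {
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges())
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric interval coordinates", call. = FALSE)
  }
  if (any(start < 0)) {
    stop("negative start coordinate", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("interval %d has start >= end (%s:%s-%s)", bad[1L],
                 chrom[bad[1L]], start[bad[1L]], end[bad[1L]]), call. = FALSE)
  }
  if (any(grepl("\\s", chrom))) {
    stop("chromosome names must not contain whitespace", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (!is.null(score)) {
    if (any(score < 0, na.rm = TRUE)) {
      stop("scores must be non-negative", call. = FALSE)
    }
    S4Vectors::mcols(gr)$score <- score
  }
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  sort_intervals(gr)
}

# deterministic sort: alphabetical chromosomes, then start
sort_intervals <- function(gr) {
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  sort(gr, ignore.strand = TRUE)
}

#' Convert intervals back to a 0-based half-open data frame
#'
#' @param gr a `GRanges`.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive) and
#'   any metadata columns.
#' @export
intervals_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md) > 0L) df <- cbind(df, md)
  df
}

#' Sample identity for a peak set
#'
#' A sample key pairs a condition label with a timepoint on the declared
#' ordered axis (see [timepoint_axis()]).
#'
#' @param condition condition label, e.g. `"dsRed"`.
#' @param timepoint timepoint label, e.g. `"D3"` or an anchor (`"MEF"`).
#' @return object of class `sample_key`.
#' @export
sample_key <- function(condition, timepoint) {
  stopifnot(is.character(condition), length(condition) == 1L,
            is.character(timepoint), length(timepoint) == 1L)
  structure(list(condition = condition, timepoint = timepoint),
            class = "sample_key")
}

#' @method format sample_key
#' @export
format.sample_key <- function(x, ...) paste0(x$condition, ":", x$timepoint)

#' @export
print.sample_key <- function(x, ...) {
  cat("<sample_key>", format(x), "\n")
  invisible(x)
}

#' A sorted set of called peaks for one sample
#'
#' @param intervals a `GRanges` (need not be disjoint).
#' @param condition,timepoint sample identity; anchors conventionally use the
#'   condition label `"ref"`.
#' @return object of class `peak_set` with elements `key` and `intervals`.
#' @export
peak_set <- function(intervals, condition = "ref", timepoint = NA_character_) {
  stopifnot(methods::is(intervals, "GRanges"))
  structure(list(key = sample_key(condition, timepoint),
                 intervals = sort_intervals(intervals)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peaks\n", format(x$key), length(x$intervals)))
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$intervals)

narrowpeak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                     "signalValue", "pValue", "qValue", "peak")

parse_peak_lines <- function(lines, format, path) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmin <- if (format == "narrowpeak") 10L else 3L
  nf <- lengths(fields)
  if (any(nf < nmin)) {
    i <- which(nf < nmin)[1L]
    stop(sprintf("%s: line %d has %d columns, expected >= %d",
                 path, lineno[i], nf[i], nmin), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d has non-integer coordinates", path,
                 lineno[bad[1L]]), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d has start >= end", path, lineno[bad[1L]]),
         call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (format == "narrowpeak") {
    out$name <- vapply(fields, `[[`, "", 4L)
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    out$signalValue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
    out$pValue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 8L)))
    out$qValue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 9L)))
    bad <- which(is.na(out$qValue))
    if (length(bad) > 0L) {
      stop(sprintf("%s: line %d has non-numeric qValue", path,
                   lineno[bad[1L]]), call. = FALSE)
    }
  }
  out
}

#' Read a peak file
#'
#' Reads BED3 or ENCODE narrowPeak (10 tab-separated columns; `qValue` in
#' column 9 stored as -log10 q). With `q_max` set on narrowPeak input, rows
#' failing the FDR threshold (`qValue < -log10(q_max)`) are dropped, mirroring
#' the peak-caller convention that only q < 0.05 regions count as open.
#'
#' @param path file path.
#' @param format `"bed3"` or `"narrowpeak"`.
#' @param q_max optional FDR ceiling (e.g. `0.05`); narrowPeak only.
#' @param condition,timepoint sample identity recorded on the result.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, format = c("bed3", "narrowpeak"), q_max = NULL,
                       condition = "ref", timepoint = NA_character_) {
  if (length(format) == 1L && !format %in% c("bed3", "narrowpeak")) {
    stop(sprintf("unknown peak format '%s'", format), call. = FALSE)
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("peak file not found: %s", path),
                               call. = FALSE)
  df <- parse_peak_lines(readLines(path), format, path)
  if (format == "narrowpeak" && !is.null(q_max)) {
    df <- df[df$qValue >= -log10(q_max), , drop = FALSE]
  }
  gr <- make_intervals(df$chrom, df$start, df$end,
                       score = if (format == "narrowpeak") df$qValue else NULL,
                       name = if (format == "narrowpeak") df$name else NULL)
  peak_set(gr, condition = condition, timepoint = timepoint)
}

#' Write peaks to BED3 or narrowPeak
#'
#' @param x a `peak_set` or `GRanges`.
#' @param path output path.
#' @param format `"bed3"` or `"narrowpeak"`. narrowPeak output fills the
#'   score/signal columns from the `score` metadata column (0 when absent)
#'   and sets the summit offset to the interval midpoint.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, format = c("bed3", "narrowpeak")) {
  format <- match.arg(format)
  gr <- if (inherits(x, "peak_set")) x$intervals else x
  df <- intervals_to_df(gr)
  if (format == "bed3") {
    out <- df[, c("chrom", "start", "end")]
  } else {
    score <- if ("score" %in% names(df)) df$score else rep(0, nrow(df))
    name <- if ("name" %in% names(df) && !anyNA(df$name)) df$name else
      sprintf("peak_%d", seq_len(nrow(df)))
    out <- data.frame(df$chrom, df$start, df$end, name,
                      as.integer(pmin(1000, round(score * 10))), ".",
                      score, score, score,
                      as.integer((df$end - df$start) %/% 2))
  }
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals into a disjoint sorted set
#'
#' @param intervals a `GRanges`.
#' @param merge_bookended join intervals at distance 0 (default `TRUE`,
#'   matching the common merge-tool default).
#' @return sorted, pairwise-disjoint `GRanges`; total covered bases are never
#'   reduced and grow only by bookend joins.
#' @export
merge_intervals <- function(intervals, merge_bookended = TRUE) {
  gap <- if (merge_bookended) 1L else 0L
  sort_intervals(GenomicRanges::reduce(intervals, min.gapwidth = gap,
                                       ignore.strand = TRUE))
}

#' Build the union atlas from several peak sets
#'
#' Merges every sample's peaks into one disjoint genome-wide interval set —
#' the row space for all downstream state matrices. Interval IDs
#' `U000001`... are assigned in (chrom, start) order.
#'
#' @param peak_sets list of [peak_set()] objects (or bare `GRanges`).
#' @return object of class `union_set`: list with `intervals` (`GRanges`,
#'   named) and `n_sources`.
#' @export
build_union <- function(peak_sets) {
  if (inherits(peak_sets, "peak_set") || methods::is(peak_sets, "GRanges")) {
    peak_sets <- list(peak_sets)
  }
  grs <- lapply(peak_sets, function(p) {
    gr <- if (inherits(p, "peak_set")) p$intervals else p
    GenomicRanges::granges(gr)
  })
  if (length(grs) == 0L || all(vapply(grs, length, 1L) == 0L)) {
    stop("all input peak sets are empty: no union atlas to build",
         call. = FALSE)
  }
  # suppress the benign seqlevel-merge notice when samples cover
  # different chromosome subsets
  merged <- merge_intervals(suppressWarnings(do.call(c, unname(grs))))
  names(merged) <- sprintf("U%06d", seq_along(merged))
  structure(list(intervals = merged, n_sources = length(peak_sets)),
            class = "union_set")
}

#' @export
print.union_set <- function(x, ...) {
  cat(sprintf("<union_set> %d disjoint intervals from %d peak sets\n",
              length(x$intervals), x$n_sources))
  invisible(x)
}

#' @export
length.union_set <- function(x) length(x$intervals)

#' Does each query interval overlap any subject interval?
#'
#' Half-open semantics: a shared base is required, adjacency does not count.
#' With `min_frac > 0`, at least that fraction of the query's bases must be
#' covered by subject intervals.
#'
#' @param query,subject `GRanges`.
#' @param min_frac minimum covered fraction of the query (default 0 = any
#'   single base).
#' @return logical vector aligned to `query`.
#' @export
overlap_any <- function(query, subject, min_frac = 0) {
  if (min_frac <= 0) {
    return(suppressWarnings(
      IRanges::overlapsAny(query, subject, ignore.strand = TRUE)))
  }
  cov <- covered_width(query, subject)
  cov / GenomicRanges::width(query) >= min_frac
}

# summed width of (query ∩ subject) per query interval, counting each base once
covered_width <- function(query, subject) {
  subject <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE))
  w <- GenomicRanges::width(suppressWarnings(IRanges::pintersect(
    query[S4Vectors::queryHits(hits)],
    subject[S4Vectors::subjectHits(hits)])))
  out <- numeric(length(query))
  if (length(hits) > 0L) {
    agg <- rowsum(w, S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Remove peaks overlapping a control set
#'
#' Background subtraction at the peak level: any peak sharing at least one
#' base with a control peak is dropped whole (no base trimming), as in
#' removing control-condition peaks from a treatment sample at the matched
#' timepoint.
#'
#' @param peaks,control [peak_set()] objects or `GRanges`.
#' @return object of the same kind as `peaks` with overlapping peaks removed.
#' @export
subtract_peaks <- function(peaks, control) {
  pgr <- if (inherits(peaks, "peak_set")) peaks$intervals else peaks
  cgr <- if (inherits(control, "peak_set")) control$intervals else control
  kept <- pgr[!suppressWarnings(
    IRanges::overlapsAny(pgr, cgr, ignore.strand = TRUE))]
  if (inherits(peaks, "peak_set")) {
    peak_set(kept, peaks$key$condition, peaks$key$timepoint)
  } else {
    kept
  }
}

#' Write a union atlas as BED4
#'
#' @param union a `union_set`.
#' @param path output path; columns chrom, start (0-based), end, interval ID.
#' @return `path`, invisibly.
#' @export
write_union_bed <- function(union, path) {
  df <- intervals_to_df(union$intervals)
  df$name <- names(union$intervals)
  write.table(df[, c("chrom", "start", "end", "name")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
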
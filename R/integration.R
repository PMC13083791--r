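# Peak-to-gene annotation, gene-set overlap enrichment, and binding-peak
# occupancy across accessibility classes.

#' Read a TSS / gene-model table
#'
#' Tab-separated with header `gene`, `chrom`, `tss` (0-based position),
#' `strand` (+/-). One primary TSS per gene: the first declared row wins and
#' later duplicates are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tss_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(df$gene)
  if (any(dup)) {
    warning(sprintf("%d duplicate TSS record(s) dropped (first wins)",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df[, need]
}

tss_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$tss + 1L, genes$tss + 1L),
                         gene = genes$gene)
}

# midpoint of 0-based half-open intervals, as 1-based single-base GRanges
midpoint_granges <- function(peaks) {
  df <- intervals_to_df(peaks)
  mid <- (df$start + df$end) %/% 2L
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
}

#' Classify peaks by genomic feature
#'
#' Assigns each peak exactly one feature class by the location of its
#' midpoint, with precedence promoter > exon > intron > distal_intergenic.
#' The promoter is the +/- `promoter_window` bases around the TSS (default
#' 3 kb). Exon/intron classification requires a declared exon table; genes
#' without exon structure contribute only promoters.
#'
#' @param peaks `GRanges` (or [peak_set()]).
#' @param genes TSS table (see [read_tss_table()]).
#' @param promoter_window half-width in bases (> 0, default 3000).
#' @param exons optional data.frame `gene`, `chrom`, `start`, `end`
#'   (0-based half-open exon intervals); gene bodies span min start to max
#'   end per gene.
#' @return character vector aligned to `peaks` with values `promoter`,
#'   `exon`, `intron`, `distal_intergenic`.
#' @export
annotate_feature <- function(peaks, genes, promoter_window = 3000,
                             exons = NULL) {
  stopifnot(promoter_window > 0)
  if (inherits(peaks, "peak_set")) peaks <- peaks$intervals
  if (nrow(genes) == 0L) stop("empty gene table", call. = FALSE)
  mid <- midpoint_granges(peaks)
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(0L, genes$tss - promoter_window) + 1L,
                     genes$tss + promoter_window))
  out <- rep("distal_intergenic", length(peaks))
  if (!is.null(exons) && nrow(exons) > 0L) {
    ex <- GenomicRanges::GRanges(exons$chrom,
                                 IRanges::IRanges(exons$start + 1L, exons$end))
    body_df <- do.call(rbind, lapply(split(exons, exons$gene), function(e) {
      data.frame(chrom = e$chrom[1L], start = min(e$start), end = max(e$end))
    }))
    body <- GenomicRanges::GRanges(
      body_df$chrom, IRanges::IRanges(body_df$start + 1L, body_df$end))
    out[IRanges::overlapsAny(mid, body)] <- "intron"
    out[IRanges::overlapsAny(mid, ex)] <- "exon"
  }
  out[IRanges::overlapsAny(mid, prom)] <- "promoter"
  out
}

#' Feature-class distribution of a peak set
#'
#' @inheritParams annotate_feature
#' @return data.frame `feature`, `count`, `proportion` over the four
#'   classes; proportions sum to 1.
#' @export
feature_distribution <- function(peaks, genes, promoter_window = 3000,
                                 exons = NULL) {
  cls <- annotate_feature(peaks, genes, promoter_window, exons)
  lev <- c("promoter", "exon", "intron", "distal_intergenic")
  n <- as.integer(table(factor(cls, levels = lev)))
  data.frame(feature = lev, count = n,
             proportion = if (sum(n) > 0) n / sum(n) else rep(0, 4L),
             stringsAsFactors = FALSE)
}

#' Link peaks to genes
#'
#' `window` mode returns every gene whose +/- `window` TSS region overlaps
#' at least one peak; `nearest` mode lets each peak contribute its
#' minimum-distance TSS gene (distance ties contribute all tied genes).
#'
#' @param peaks `GRanges` or [peak_set()].
#' @param genes TSS table.
#' @param mode `"window"` (default) or `"nearest"`.
#' @param window half-width in bases for window mode (default 3000).
#' @return sorted character vector of linked gene identifiers.
#' @export
link_peaks_to_genes <- function(peaks, genes, mode = c("window", "nearest"),
                                window = 3000) {
  mode <- match.arg(mode)
  if (inherits(peaks, "peak_set")) peaks <- peaks$intervals
  if (length(peaks) == 0L) return(character())
  tss <- tss_granges(genes)
  if (mode == "window") {
    stopifnot(window > 0)
    # [tss - w, tss + w) in 0-based half-open coordinates
    win <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(0L, genes$tss - window) + 1L, genes$tss + window))
    hit <- IRanges::overlapsAny(win, peaks)
    sort(unique(genes$gene[hit]))
  } else {
    h <- GenomicRanges::distanceToNearest(peaks, tss)
    if (length(h) == 0L) return(character())
    # widen each peak by its min distance so equidistant TSSs tie in
    d <- S4Vectors::mcols(h)$distance
    qi <- S4Vectors::queryHits(h)
    widened <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(peaks)[qi],
      IRanges::IRanges(pmax(1L, GenomicRanges::start(peaks)[qi] - d - 1L),
                       GenomicRanges::end(peaks)[qi] + d + 1L))
    hits <- GenomicRanges::findOverlaps(widened, tss, ignore.strand = TRUE)
    sort(unique(genes$gene[S4Vectors::subjectHits(hits)]))
  }
}

#' Gene-set overlap with hypergeometric enrichment
#'
#' Overlap members plus the upper-tail hypergeometric p-value
#' `P(X >= k)` for drawing `|set_b|` genes from a universe of
#' `|universe|` containing `|set_a|` successes.
#'
#' @param set_a,set_b character vectors of gene identifiers; must be subsets
#'   of `universe`.
#' @param universe background gene identifiers.
#' @return list of class `overlap_result`: sizes, `overlap_size`,
#'   `members`, `p_enrich`.
#' @export
gene_set_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("gene sets must be subsets of the universe", call. = FALSE)
  }
  members <- sort(intersect(set_a, set_b))
  k <- length(members)
  p <- stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  structure(list(set_a_size = length(set_a), set_b_size = length(set_b),
                 universe_size = length(universe), overlap_size = k,
                 members = members, p_enrich = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> |A|=%d |B|=%d overlap=%d universe=%d p=%.3g\n",
    x$set_a_size, x$set_b_size, x$overlap_size, x$universe_size, x$p_enrich))
  invisible(x)
}

#' Binding-peak occupancy by accessibility class
#'
#' Each binding peak is assigned to the class region set it overlaps most
#' (largest covered width; ties go to the earlier class in list order) or to
#' `outside` when it overlaps none. Reports per class the raw fraction of
#' all binding peaks and the region-count-normalized occupancy
#' (overlapping peaks / number of regions in the class), which corrects for
#' classes of very different sizes.
#'
#' @param binding_peaks `GRanges` or [peak_set()].
#' @param class_regions named list of disjoint `GRanges`, e.g.
#'   `list(PO = ..., OC = ..., CO = ...)`; regions must not overlap across
#'   classes (they partition the atlas).
#' @return data.frame `atac_class`, `n_regions`, `n_overlapping_peaks`,
#'   `raw_fraction`, `normalized` (NA for the `outside` bin); raw fractions
#'   sum to 1 whenever any peak is present.
#' @export
occupancy_by_class <- function(binding_peaks, class_regions) {
  if (inherits(binding_peaks, "peak_set")) binding_peaks <- binding_peaks$intervals
  stopifnot(is.list(class_regions), !is.null(names(class_regions)))
  all_regions <- suppressWarnings(
    do.call(c, unname(lapply(class_regions, GenomicRanges::granges))))
  if (length(GenomicRanges::reduce(all_regions, min.gapwidth = 0L,
                                   ignore.strand = TRUE)) <
      length(all_regions)) {
    # no gap tolerance: joins only true overlaps, never bookended regions
    stop("class regions overlap across classes: not a partition",
         call. = FALSE)
  }
  n_peaks <- length(binding_peaks)
  cover <- vapply(class_regions, function(gr) {
    covered_width(binding_peaks, gr)
  }, numeric(n_peaks))
  cover <- matrix(cover, nrow = n_peaks)
  best <- apply(cover, 1L, function(w) {
    if (all(w == 0)) 0L else which.max(w)  # which.max takes the earliest tie
  })
  classes <- names(class_regions)
  assigned <- factor(c("outside", classes)[best + 1L],
                     levels = c(classes, "outside"))
  counts <- as.integer(table(assigned))
  n_regions <- c(vapply(class_regions, length, 1L), NA_integer_)
  data.frame(
    atac_class = c(classes, "outside"),
    n_regions = n_regions,
    n_overlapping_peaks = counts,
    raw_fraction = if (n_peaks > 0) counts / n_peaks else rep(0, length(counts)),
    normalized = ifelse(is.na(n_regions), NA_real_, counts / n_regions),
    stringsAsFactors = FALSE
  )
}

#' Split an atlas into per-class region sets
#'
#' Groups a module assignment's intervals by base class for use with
#' [occupancy_by_class()].
#'
#' @param union a `union_set`.
#' @param assignment a [classify_condition()] result over the same atlas.
#' @param classes base classes to keep (default PO, OC, CO).
#' @return named list of `GRanges`.
#' @export
class_regions_from_assignment <- function(union, assignment,
                                          classes = c("PO", "OC", "CO")) {
  stopifnot(length(union$intervals) == length(assignment$base))
  setNames(lapply(classes, function(cl) {
    union$intervals[assignment$base == cl]
  }), classes)
}
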
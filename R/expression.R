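# Cross-system differential-expression modules: per-timepoint direction
# calls, within-system consistency filtering, common/specific categorization
# across perturbation systems, anchor-expression binning, and peak-timepoint
# ranking.

#' Read a differential-expression table
#'
#' Expects a tab-separated file with header columns `gene`, `system`,
#' `timepoint`, `log2fc`, `pvalue` (one row per gene x system x timepoint,
#' fold changes relative to the control arm at the same timepoint).
#'
#' @param path file path.
#' @return data.frame of differential records.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("DE table not found: %s", path),
                               call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("gene", "system", "timepoint", "log2fc", "pvalue")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$log2fc) | is.na(df$pvalue))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d has non-numeric log2fc/pvalue", path,
                 bad[1L] + 1L), call. = FALSE)
  }
  dup <- duplicated(df[, c("gene", "system", "timepoint")])
  if (any(dup)) {
    stop(sprintf("%s: duplicate (gene, system, timepoint) record at line %d",
                 path, which(dup)[1L] + 1L), call. = FALSE)
  }
  df[, need]
}

#' Read a reference (anchor) expression table
#'
#' Tab-separated with header `gene`, `expr_mef`, `expr_esc` — normalized
#' expression in the start- and end-state reference samples.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ref_expr <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "expr_mef", "expr_esc")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[, need]
}

#' Per-record direction calls
#'
#' A record is `up` iff `log2fc > lfc_min` and `pvalue < p_max`; `down`
#' symmetric; otherwise `ns`. Defaults follow the common significance gate
#' p < 0.05 with |log2 fold change| > 1. With `adjust = TRUE`, p-values are
#' Benjamini-Hochberg corrected within each (system, timepoint) before
#' thresholding.
#'
#' @param records data.frame with `gene`, `system`, `timepoint`, `log2fc`,
#'   `pvalue`.
#' @param p_max p-value ceiling in (0,1), default 0.05.
#' @param lfc_min absolute log2 fold-change floor (> 0), default 1.
#' @param adjust apply BH correction within (system, timepoint).
#' @return the input with a `call` column (`up`/`down`/`ns`).
#' @export
call_directions <- function(records, p_max = 0.05, lfc_min = 1,
                            adjust = FALSE) {
  stopifnot(p_max > 0, p_max < 1, lfc_min > 0)
  if (any(records$pvalue < 0 | records$pvalue > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p <- records$pvalue
  if (adjust) {
    grp <- interaction(records$system, records$timepoint, drop = TRUE)
    p <- unsplit(lapply(split(p, grp), p.adjust, method = "BH"), grp)
  }
  sig <- p < p_max
  records$call <- ifelse(sig & records$log2fc > lfc_min, "up",
                         ifelse(sig & records$log2fc < -lfc_min, "down", "ns"))
  records
}

#' Collapse timepoint calls to one direction per (gene, system)
#'
#' Genes with opposing significant directions at different timepoints within
#' the same system are `excluded` (inconsistent regulation); otherwise the
#' direction is `up`/`down` if any timepoint reached it, else `ns`.
#'
#' @param calls output of [call_directions()].
#' @return data.frame `gene`, `system`, `direction`
#'   (`up`/`down`/`ns`/`excluded`).
#' @export
consistency_filter <- function(calls) {
  key <- interaction(calls$gene, calls$system, drop = TRUE, sep = "\r")
  any_up <- tapply(calls$call == "up", key, any)
  any_dn <- tapply(calls$call == "down", key, any)
  parts <- strsplit(names(any_up), "\r", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    system = vapply(parts, `[[`, "", 2L),
    direction = ifelse(any_up & any_dn, "excluded",
                       ifelse(any_up, "up", ifelse(any_dn, "down", "ns"))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Categorize one gene's per-system directions
#'
#' Truth table over directions in each declared system: all `up` =>
#' `common_up`; exactly two `up`, rest `ns` => `pair_up(S1&S2)`; exactly one
#' `up`, rest `ns` => `specific_up(S)`; symmetric for `down`; any mix of
#' `up` and `down`, or any `excluded`, => `discordant`; all `ns` => `none`.
#'
#' @param directions character vector of directions aligned to `systems`
#'   (values `up`/`down`/`ns`/`excluded`).
#' @param systems system labels.
#' @return list with `class` (the cell name), `members` (systems driving
#'   it), `category` (printable label, e.g. `"pair_up(Low&High)"`).
#' @export
categorize_directions <- function(directions, systems) {
  stopifnot(length(directions) == length(systems))
  ok <- directions %in% c("up", "down", "ns", "excluded")
  if (!all(ok)) stop("unknown direction value", call. = FALSE)
  n <- length(systems)
  up <- directions == "up"
  dn <- directions == "down"
  exc <- directions == "excluded"
  # after the discordant and common cells, only up+ns or down+ns mixes remain
  cls <- if (any(exc) || (any(up) && any(dn))) {
    list(class = "discordant", members = systems[up | dn | exc])
  } else if (sum(up) == n) {
    list(class = "common_up", members = systems)
  } else if (sum(dn) == n) {
    list(class = "common_down", members = systems)
  } else if (sum(up) >= 2L) {
    list(class = "pair_up", members = systems[up])
  } else if (sum(dn) >= 2L) {
    list(class = "pair_down", members = systems[dn])
  } else if (sum(up) == 1L) {
    list(class = "specific_up", members = systems[up])
  } else if (sum(dn) == 1L) {
    list(class = "specific_down", members = systems[dn])
  } else {
    list(class = "none", members = character())
  }
  cls$members <- sort(cls$members)  # canonical member order
  cls$category <- if (cls$class %in% c("pair_up", "pair_down",
                                       "specific_up", "specific_down")) {
    sprintf("%s(%s)", cls$class, paste(cls$members, collapse = "&"))
  } else {
    cls$class
  }
  cls
}

#' Cross-system categories for all genes
#'
#' Genes absent from a system's calls are treated as `ns` there.
#'
#' @param system_calls output of [consistency_filter()] (possibly several
#'   systems row-bound).
#' @param systems declared system labels (default: those present).
#' @return data.frame `gene`, `class`, `category`, `members` (`&`-joined).
#' @export
cross_system_categorize <- function(system_calls,
                                    systems = sort(unique(system_calls$system))) {
  missing <- setdiff(unique(system_calls$system), systems)
  if (length(missing) > 0L) {
    stop(sprintf("calls contain undeclared system(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  genes <- sort(unique(system_calls$gene))
  dir_mat <- matrix("ns", nrow = length(genes), ncol = length(systems),
                    dimnames = list(genes, systems))
  idx <- cbind(match(system_calls$gene, genes),
               match(system_calls$system, systems))
  dir_mat[idx] <- system_calls$direction
  res <- lapply(seq_along(genes), function(i) {
    categorize_directions(dir_mat[i, ], systems)
  })
  data.frame(
    gene = genes,
    class = vapply(res, `[[`, "", "class"),
    category = vapply(res, `[[`, "", "category"),
    members = vapply(res, function(r) paste(r$members, collapse = "&"), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Bin genes by anchor-state expression ratio
#'
#' `ESC_high` if (expr_esc + eps) / (expr_mef + eps) >= fc, `MEF_high` if
#' the ratio <= 1/fc, else `neutral`. The default two-fold cut reflects the
#' usual anchor-binning convention; `eps` guards zero expression on
#' RPKM-scale values.
#'
#' @param expr_mef,expr_esc non-negative expression vectors.
#' @param fc fold-change cut (> 1, default 2).
#' @param eps pseudocount (default 1).
#' @return character vector: `ESC_high` / `MEF_high` / `neutral`.
#' @export
anchor_bin <- function(expr_mef, expr_esc, fc = 2, eps = 1) {
  stopifnot(fc > 1)
  if (any(expr_mef < 0 | expr_esc < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  ratio <- (expr_esc + eps) / (expr_mef + eps)
  ifelse(ratio >= fc, "ESC_high", ifelse(ratio <= 1 / fc, "MEF_high",
                                         "neutral"))
}

#' Peak-timepoint ranking key for module ordering
#'
#' Up-regulated genes are keyed by the timepoint of their maximum
#' expression, down-regulated genes by their minimum; ties break to the
#' earliest timepoint. The returned order sorts by key timepoint, then by
#' magnitude (extreme value) descending for up / ascending for down.
#'
#' @param expr numeric matrix, genes x timepoints (columns in axis order).
#' @param direction `"up"` or `"down"`.
#' @return data.frame `gene`, `rank_timepoint`, `magnitude`, `order`
#'   (permutation sorting the genes).
#' @export
rank_genes <- function(expr, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.null(dim(expr)) || ncol(expr) == 0L || nrow(expr) == 0L) {
    stop("empty expression trajectory", call. = FALSE)
  }
  tps <- colnames(expr)
  if (is.null(tps)) tps <- paste0("T", seq_len(ncol(expr)))
  pick <- if (direction == "up") max.col(expr, ties.method = "first") else
    max.col(-expr, ties.method = "first")
  magnitude <- expr[cbind(seq_len(nrow(expr)), pick)]
  ord <- if (direction == "up") order(pick, -magnitude) else
    order(pick, magnitude)
  data.frame(
    gene = if (!is.null(rownames(expr))) rownames(expr) else
      as.character(seq_len(nrow(expr))),
    rank_timepoint = tps[pick],
    magnitude = magnitude,
    order = ord,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Full expression-module pipeline
#'
#' Direction calls, consistency filtering, and cross-system categorization
#' in one step; optionally adds anchor bins when a reference table is given.
#'
#' @param records differential records (see [read_de_table()]).
#' @param systems declared system labels.
#' @param ref_expr optional reference expression data.frame
#'   (`gene`, `expr_mef`, `expr_esc`).
#' @param p_max,lfc_min,adjust passed to [call_directions()].
#' @param fc,eps passed to [anchor_bin()].
#' @return list with `calls`, `system_calls`, `categories` (with
#'   `anchor_bin` column when `ref_expr` given).
#' @export
categorize_expression <- function(records,
                                  systems = sort(unique(records$system)),
                                  ref_expr = NULL, p_max = 0.05, lfc_min = 1,
                                  adjust = FALSE, fc = 2, eps = 1) {
  calls <- call_directions(records, p_max = p_max, lfc_min = lfc_min,
                           adjust = adjust)
  sys_calls <- consistency_filter(calls)
  categories <- cross_system_categorize(sys_calls, systems = systems)
  if (!is.null(ref_expr)) {
    m <- match(categories$gene, ref_expr$gene)
    categories$anchor_bin <- ifelse(
      is.na(m), NA_character_,
      anchor_bin(ref_expr$expr_mef[m], ref_expr$expr_esc[m], fc = fc,
                 eps = eps))
  }
  list(calls = calls, system_calls = sys_calls, categories = categories)
}
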
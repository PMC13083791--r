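# Open/closed state matrices over the union atlas, and the state-transition
# classifier: base class from the MEF/ESC anchors, timing submodule from the
# earliest timepoint at which an interval adopts and thereafter maintains the
# endpoint state.

#' Declare the ordered timepoint axis
#'
#' The axis carries the time-course order plus exactly one start anchor and
#' one end anchor (defaults: first and last element). The canonical
#' reprogramming axis is `MEF, D0, D3, D5, D7, ESC` with MEF/ESC anchors.
#'
#' @param timepoints ordered character vector of timepoint labels.
#' @param start_anchor,end_anchor anchor labels; must be members of
#'   `timepoints`.
#' @return object of class `timepoint_axis` with elements `timepoints`,
#'   `start_anchor`, `end_anchor`, `inner` (non-anchor timepoints in order)
#'   and `K` (number of timing submodules = `length(inner) + 1`).
#' @export
timepoint_axis <- function(timepoints = c("MEF", "D0", "D3", "D5", "D7", "ESC"),
                           start_anchor = timepoints[1L],
                           end_anchor = timepoints[length(timepoints)]) {
  stopifnot(is.character(timepoints), length(timepoints) >= 3L,
            !anyDuplicated(timepoints))
  if (!start_anchor %in% timepoints || !end_anchor %in% timepoints ||
      identical(start_anchor, end_anchor)) {
    stop("axis needs two distinct anchors drawn from the timepoints",
         call. = FALSE)
  }
  inner <- setdiff(timepoints, c(start_anchor, end_anchor))
  structure(list(timepoints = timepoints, start_anchor = start_anchor,
                 end_anchor = end_anchor, inner = inner,
                 K = length(inner) + 1L),
            class = "timepoint_axis")
}

#' @export
print.timepoint_axis <- function(x, ...) {
  cat(sprintf("<timepoint_axis> %s (anchors %s -> %s, K=%d)\n",
              paste(x$timepoints, collapse = " "), x$start_anchor,
              x$end_anchor, x$K))
  invisible(x)
}

sample_col_id <- function(condition, timepoint) paste0(condition, ":", timepoint)

#' Call the boolean open/closed state matrix
#'
#' A union interval is "open" in a sample iff it overlaps that sample's
#' called peaks (by at least one base, or at least `min_overlap` of its
#' length). All other intervals are closed. Anchor samples (at the axis's
#' start/end anchor timepoints) must be present; each (condition, timepoint)
#' pair may appear only once.
#'
#' @param union a [build_union()] result.
#' @param peak_sets list of [peak_set()] objects covering all samples.
#' @param axis a [timepoint_axis()].
#' @param min_overlap minimum covered fraction of the union interval
#'   (default 0 = any shared base).
#' @return object of class `state_matrix`: `union`, `samples` (data.frame
#'   condition/timepoint), `states` (logical interval x sample matrix), `axis`.
#' @export
call_state_matrix <- function(union, peak_sets, axis = timepoint_axis(),
                              min_overlap = 0) {
  stopifnot(inherits(union, "union_set"), inherits(axis, "timepoint_axis"))
  samples <- data.frame(
    condition = vapply(peak_sets, function(p) p$key$condition, ""),
    timepoint = vapply(peak_sets, function(p) p$key$timepoint, ""),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(samples$timepoint, axis$timepoints)
  if (length(unknown) > 0L) {
    stop(sprintf("timepoint(s) not on the declared axis: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ids <- sample_col_id(samples$condition, samples$timepoint)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample key: %s", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  for (anchor in c(axis$start_anchor, axis$end_anchor)) {
    if (sum(samples$timepoint == anchor) != 1L) {
      stop(sprintf("exactly one shared %s anchor sample is required", anchor),
           call. = FALSE)
    }
  }
  states <- vapply(peak_sets, function(p) {
    overlap_any(union$intervals, p$intervals, min_frac = min_overlap)
  }, logical(length(union$intervals)))
  states <- matrix(states, nrow = length(union$intervals),
                   dimnames = list(names(union$intervals), ids))
  structure(list(union = union, samples = samples, states = states,
                 axis = axis),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix> %d intervals x %d samples (%.1f%% open)\n",
              nrow(x$states), ncol(x$states), 100 * mean(x$states)))
  invisible(x)
}

#' Base class from the two anchor states
#'
#' @param start_open,end_open logical vectors: open at the start (MEF) and
#'   end (ESC) anchors.
#' @return character vector: `PO` (open/open), `OC` (open/closed), `CO`
#'   (closed/open), `NE` (closed/closed — outside the three transition
#'   classes, kept so every interval is labelled).
#' @export
classify_endpoint <- function(start_open, end_open) {
  stopifnot(length(start_open) == length(end_open))
  ifelse(start_open,
         ifelse(end_open, "PO", "OC"),
         ifelse(end_open, "CO", "NE"))
}

#' Timing submodule from a state trajectory
#'
#' Returns the earliest position from which the trajectory equals the
#' endpoint state through the end: submodule `t` means the interval adopts
#' the endpoint state at inner timepoint `t` (1 = first inner timepoint,
#' e.g. D0) and maintains it; `K` means endpoint-only. Flickers reset the
#' clock — the latest maintained suffix wins.
#'
#' @param trajectory logical matrix (rows = intervals, columns = inner
#'   timepoints in order, then the end anchor) or a logical vector for one
#'   interval.
#' @param endpoint_state logical vector (recycled): the end-anchor state.
#' @return integer vector of submodule indices in `1..K`.
#' @export
assign_timing <- function(trajectory, endpoint_state) {
  if (is.vector(trajectory)) trajectory <- matrix(trajectory, nrow = 1L)
  K <- ncol(trajectory)
  endpoint_state <- rep_len(endpoint_state, nrow(trajectory))
  if (any(trajectory[, K] != endpoint_state)) {
    stop("trajectory's final state must equal the endpoint state",
         call. = FALSE)
  }
  mism <- trajectory != endpoint_state
  last_mism <- integer(nrow(trajectory))
  for (j in seq_len(K - 1L)) {
    last_mism[mism[, j]] <- j
  }
  last_mism + 1L
}

module_label_str <- function(base, submodule) {
  ifelse(base %in% c("OC", "CO"), paste0(base, submodule), base)
}

#' Classify every union interval for one condition
#'
#' The base class (PO/OC/CO/NE) comes from the shared start/end anchor
#' samples; the timing submodule (OC/CO only) from the condition's own inner
#' time-course states followed by the shared end-anchor state.
#'
#' @param matrix_ a [call_state_matrix()] result.
#' @param condition condition whose trajectory drives the timing.
#' @param require_detection if `TRUE`, intervals open in none of the
#'   condition's own samples nor the anchors are forced to `NE` (a
#'   detectability filter; default off).
#' @return object of class `module_assignment`: `condition`, `interval_id`,
#'   `base` (character), `submodule` (integer or NA), `label` (e.g. `"CO2"`),
#'   `anchors` (the anchor sample ids used), `K`.
#' @export
classify_condition <- function(matrix_, condition, require_detection = FALSE) {
  stopifnot(inherits(matrix_, "state_matrix"))
  axis <- matrix_$axis
  smp <- matrix_$samples
  if (!condition %in% smp$condition[!smp$timepoint %in%
                                    c(axis$start_anchor, axis$end_anchor)]) {
    stop(sprintf("condition '%s' has no time-course samples in the matrix",
                 condition), call. = FALSE)
  }
  start_col <- which(smp$timepoint == axis$start_anchor)
  end_col <- which(smp$timepoint == axis$end_anchor)
  inner_ids <- sample_col_id(condition, axis$inner)
  missing <- setdiff(inner_ids, colnames(matrix_$states))
  if (length(missing) > 0L) {
    stop(sprintf("condition '%s' is missing timepoint sample(s): %s",
                 condition, paste(missing, collapse = ", ")), call. = FALSE)
  }
  s_open <- unname(matrix_$states[, start_col])
  e_open <- unname(matrix_$states[, end_col])
  base <- classify_endpoint(s_open, e_open)
  traj <- cbind(matrix_$states[, inner_ids, drop = FALSE], e_open)
  submodule <- rep(NA_integer_, length(base))
  dyn <- base %in% c("OC", "CO")
  if (any(dyn)) {
    submodule[dyn] <- assign_timing(traj[dyn, , drop = FALSE], e_open[dyn])
  }
  if (require_detection) {
    detected <- rowSums(traj) > 0 | s_open
    base[!detected] <- "NE"
    submodule[!detected] <- NA_integer_
  }
  structure(list(condition = condition,
                 interval_id = rownames(matrix_$states),
                 base = base, submodule = submodule,
                 label = module_label_str(base, submodule),
                 anchors = colnames(matrix_$states)[c(start_col, end_col)],
                 K = axis$K),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %s: %d intervals\n", x$condition,
              length(x$label)))
  print(table(x$label))
  invisible(x)
}

#' @method as.data.frame module_assignment
#' @export
as.data.frame.module_assignment <- function(x, ...) {
  data.frame(interval_id = x$interval_id, condition = x$condition,
             base_class = x$base, submodule = x$submodule, label = x$label,
             stringsAsFactors = FALSE)
}

module_levels <- function(K) {
  c("PO", paste0("OC", seq_len(K)), paste0("CO", seq_len(K)), "NE")
}

#' Count intervals per module for each condition
#'
#' @param assignments list of [classify_condition()] results over the same
#'   union atlas.
#' @return data.frame: one row per condition, columns `PO`, `OC1..OCK`,
#'   `CO1..COK`, `NE`; every row sums to the union size.
#' @export
count_modules <- function(assignments) {
  if (inherits(assignments, "module_assignment")) assignments <- list(assignments)
  ids <- lapply(assignments, `[[`, "interval_id")
  if (length(unique(vapply(ids, function(x) paste(x, collapse = ","), ""))) > 1L) {
    stop("assignments cover different union sets", call. = FALSE)
  }
  K <- assignments[[1L]]$K
  lev <- module_levels(K)
  rows <- lapply(assignments, function(a) {
    as.integer(table(factor(a$label, levels = lev)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- lev
  out <- cbind(condition = vapply(assignments, `[[`, "", "condition"), out)
  rownames(out) <- NULL
  out
}

#' Cross-condition membership partition (Venn cells) for a module subset
#'
#' For every non-empty combination of (non-excluded) conditions, counts the
#' union intervals whose label lies in `classes` for exactly that
#' combination. Excluded conditions are ignored entirely, so the all-shared
#' cell of the reduced partition answers "shared by the remaining conditions
#' after excluding X".
#'
#' @param assignments list of [classify_condition()] results (>= 2 after
#'   exclusion).
#' @param classes module labels defining membership, e.g.
#'   `paste0("OC", 1:5)`.
#' @param exclude condition labels to drop before partitioning.
#' @return data.frame with `combination` (condition labels joined by `&`),
#'   `n_conditions`, and `count`; attribute `set_sizes` gives each
#'   condition's membership-set size.
#' @export
module_venn <- function(assignments, classes, exclude = character()) {
  if (length(classes) == 0L) stop("empty module class subset", call. = FALSE)
  conds <- vapply(assignments, `[[`, "", "condition")
  keep <- !conds %in% exclude
  assignments <- assignments[keep]
  conds <- conds[keep]
  if (length(assignments) < 2L) {
    stop("need at least two conditions after exclusion", call. = FALSE)
  }
  member <- vapply(assignments, function(a) a$label %in% classes,
                   logical(length(assignments[[1L]]$label)))
  member <- matrix(member, ncol = length(conds), dimnames = list(NULL, conds))
  in_any <- rowSums(member) > 0
  combo <- apply(member[in_any, , drop = FALSE], 1L, function(m) {
    paste(conds[m], collapse = "&")
  })
  tab <- table(combo)
  out <- data.frame(combination = names(tab),
                    n_conditions = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n_conditions, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_sizes") <- colSums(member)
  out
}

#' Count intervals shared by a set of conditions
#'
#' Convenience wrapper over the same membership matrix as [module_venn()]:
#' how many intervals carry a label in `classes` in every condition of
#' `among` (other conditions ignored, i.e. "shared after excluding" them).
#'
#' @inheritParams module_venn
#' @param among condition labels that must all contain the interval.
#' @return integer count.
#' @export
venn_shared <- function(assignments, classes, among) {
  conds <- vapply(assignments, `[[`, "", "condition")
  missing <- setdiff(among, conds)
  if (length(missing) > 0L) {
    stop(sprintf("condition(s) not assigned: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  member <- vapply(assignments[match(among, conds)],
                   function(a) a$label %in% classes,
                   logical(length(assignments[[1L]]$label)))
  sum(rowSums(matrix(member, ncol = length(among))) == length(among))
}
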
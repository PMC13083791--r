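# Seeded synthetic-data generator with planted ground truth: time-course
# peak files with module structure and state-call noise, differential
# expression tables with planted cross-system categories, anchor expression,
# TSS tables, and class-biased binding peaks.

# Stable per-stage substream: a label-hashed offset on the root seed, so
# adding a stage never perturbs earlier draws. Result stays far below 2^31.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  (as.integer(seed) %% 1000003L) * 1000L + h
}

#' Default simulation configuration
#'
#' The defaults mirror the study design the analysis assumes: a
#' `MEF, D0, D3, D5, D7, ESC` axis, four conditions (one control plus three
#' treatment arms), interval lengths of 200-1000 bases, planted
#' common/specific differentially expressed genes with log2 effects around
#' 2, and class-biased binding rates (PO 0.30, OC 0.10, CO 0.05).
#'
#' @param seed root random seed (mandatory for any simulation).
#' @return nested list of class `sim_config`; see the package vignette for
#'   field-by-field documentation.
#' @export
default_sim_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = c(chrS1 = 30e6, chrS2 = 20e6),
    axis = list(timepoints = c("MEF", "D0", "D3", "D5", "D7", "ESC"),
                start_anchor = "MEF", end_anchor = "ESC"),
    conditions = c("dsRed", "RoraLow", "RoraHigh", "RoraDeltaNTD"),
    modules = c(PO = 1500, OC1 = 300, OC2 = 300, OC3 = 300, OC4 = 300,
                OC5 = 300, CO1 = 300, CO2 = 300, CO3 = 300, CO4 = 300,
                CO5 = 300, NE = 500),
    interval_length = c(min = 200, max = 1000),
    gap = c(min = 200, max = 2000),
    flicker_noise = 0,
    timing_shift = NULL,
    de = list(
      genes = c(common_up = 60, common_down = 60, specific_up = 30,
                specific_down = 30, pair_up = 15, pair_down = 15,
                null = 1000),
      lfc_mean = 2.0, lfc_sd = 0.5, lfc_gate = 1.0,
      p_planted_max = 1e-4, null_lfc_sd = 0.25,
      p_gate = 0.05),
    binding = list(rates = c(PO = 0.30, OC = 0.10, CO = 0.05)),
    tss = list(n_genes = 400, body_length = c(min = 2000, max = 20000))
  ), class = "sim_config")
}

#' Validate (and complete) a simulation configuration
#'
#' @param config a list as from [default_sim_config()] or parsed JSON;
#'   missing fields are filled from the defaults. `seed` is mandatory.
#' @return validated `sim_config`.
#' @export
validate_sim_config <- function(config) {
  if (is.null(config$seed)) stop("config field 'seed' is required",
                                 call. = FALSE)
  base <- default_sim_config(config$seed)
  config <- utils::modifyList(unclass(base), config)
  config$modules <- unlist(config$modules)
  config$genome <- unlist(config$genome)
  config$de$genes <- unlist(config$de$genes)
  config$binding$rates <- unlist(config$binding$rates)
  config$interval_length <- unlist(config$interval_length)
  config$gap <- unlist(config$gap)
  config$tss$body_length <- unlist(config$tss$body_length)
  for (field in c("modules", "genome")) {
    if (is.null(names(config[[field]]))) {
      stop(sprintf("config field '%s' must be a named mapping", field),
           call. = FALSE)
    }
  }
  if (any(config$modules < 0) || any(config$de$genes < 0)) {
    stop("module/gene counts must be >= 0", call. = FALSE)
  }
  if (config$flicker_noise < 0 || config$flicker_noise > 1) {
    stop("flicker_noise must lie in [0, 1]", call. = FALSE)
  }
  if (any(config$binding$rates < 0 | config$binding$rates > 1)) {
    stop("binding rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(config$genome <= 0)) stop("chromosome lengths must be positive",
                                    call. = FALSE)
  ax <- config$axis
  config$axis_obj <- timepoint_axis(ax$timepoints, ax$start_anchor,
                                    ax$end_anchor)
  K <- config$axis_obj$K
  lev <- module_levels(K)
  unknown <- setdiff(names(config$modules), lev)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown module label(s) in config: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(config, class = "sim_config")
}

#' Write a simulation config to JSON
#'
#' Named vectors (module counts, chromosome lengths, binding rates, ...)
#' are serialized as JSON objects so that names survive the round trip.
#'
#' @param config a `sim_config` or compatible list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (!is.null(names(x)) && length(x) > 0L) as.list(x)
    else x
  }
  keep <- setdiff(names(config), "axis_obj")
  jsonlite::write_json(named_to_list(unclass(config)[keep]), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation config from JSON
#'
#' @param path JSON file matching the [default_sim_config()] structure.
#' @return validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  validate_sim_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

# inner positions transiently open for NE intervals (closed at both anchors;
# they enter the union atlas through this transient accessibility)
ne_open_positions <- function(n_inner) {
  p <- ceiling(n_inner / 2)
  unique(c(p, min(p + 1L, n_inner)))
}

#' True open/closed trajectory for a planted module label
#'
#' Returns the full state vector (start anchor, inner timepoints, end
#' anchor) implied by a base class and timing submodule: OC/CO intervals
#' adopt the endpoint state at inner position `submodule` and maintain it;
#' PO is always open; NE is closed at the anchors but transiently open
#' mid-course.
#'
#' @param base `"PO"`, `"OC"`, `"CO"` or `"NE"`.
#' @param submodule timing index in `1..K` (OC/CO only).
#' @param K number of submodules (inner timepoints + 1).
#' @return logical vector of length `K + 1` (anchors included).
#' @export
true_trajectory <- function(base, submodule = NA_integer_, K = 5L) {
  n_inner <- K - 1L
  inner <- switch(base,
    PO = rep(TRUE, n_inner),
    NE = seq_len(n_inner) %in% ne_open_positions(n_inner),
    OC = seq_len(n_inner) < submodule,
    CO = seq_len(n_inner) >= submodule,
    stop("unknown base class"))
  start_open <- base %in% c("PO", "OC")
  end_open <- base %in% c("PO", "CO")
  c(start_open, inner, end_open)
}

place_intervals <- function(config, n) {
  len <- round(runif(n, config$interval_length["min"],
                     config$interval_length["max"]))
  gap <- round(runif(n, config$gap["min"], config$gap["max"]))
  chroms <- names(config$genome)
  chrom <- character(n); start <- numeric(n)
  ci <- 1L; cursor <- 0
  for (i in seq_len(n)) {
    repeat {
      if (ci > length(chroms)) {
        stop("genome too small for requested interval counts and gaps",
             call. = FALSE)
      }
      pos <- cursor + gap[i]
      if (pos + len[i] <= config$genome[ci]) break
      ci <- ci + 1L; cursor <- 0
    }
    chrom[i] <- chroms[ci]
    start[i] <- cursor + gap[i]
    cursor <- start[i] + len[i]
  }
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Simulate time-course accessibility peak files with planted modules
#'
#' Places disjoint union intervals on the synthetic genome, assigns each a
#' planted module label (per condition; optionally reshuffled by
#' `timing_shift`), derives every sample's true open/closed state from the
#' label's trajectory, flips each state call independently with probability
#' `flicker_noise`, and emits a peak covering the interval for every open
#' call. Anchor samples (condition `"ref"`) are shared across conditions.
#'
#' @param config a validated [default_sim_config()].
#' @param out_dir optional directory: writes one narrowPeak per sample plus
#'   `truth_accessibility.tsv`.
#' @return list with `peak_sets` (list of [peak_set()]), `truth`
#'   (data.frame: coordinates, shared `base`, per-condition planted
#'   `label_<condition>`), `files` (paths written, or NULL).
#' @export
simulate_accessibility <- function(config, out_dir = NULL) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "accessibility"))
  axis <- config$axis_obj
  K <- axis$K
  mods <- config$modules[config$modules > 0]
  n <- sum(mods)
  if (n == 0L) stop("no intervals requested", call. = FALSE)
  coords <- place_intervals(config, n)
  labels <- sample(rep(names(mods), times = mods))
  base <- sub("[0-9]+$", "", labels)
  submodule <- suppressWarnings(as.integer(sub("^(OC|CO)", "", labels)))

  # per-condition planted labels; timing_shift resamples OC/CO submodules
  cond_sub <- lapply(config$conditions, function(cond) {
    ts <- config$timing_shift[[cond]]
    if (is.null(ts)) return(submodule)
    out <- submodule
    for (cl in intersect(names(ts), c("OC", "CO"))) {
      idx <- which(base == cl)
      if (length(idx) > 0L) {
        out[idx] <- sample(seq_len(K), length(idx), replace = TRUE,
                           prob = ts[[cl]])
      }
    }
    out
  })
  names(cond_sub) <- config$conditions

  truth <- data.frame(coords, base = base, stringsAsFactors = FALSE)
  for (cond in config$conditions) {
    truth[[paste0("label_", cond)]] <- module_label_str(base, cond_sub[[cond]])
  }

  # sample plan: shared anchors + each condition's inner timepoints
  plan <- rbind(
    data.frame(condition = "ref",
               timepoint = c(axis$start_anchor, axis$end_anchor)),
    expand.grid(condition = config$conditions, timepoint = axis$inner,
                stringsAsFactors = FALSE)
  )
  peak_sets <- vector("list", nrow(plan))
  for (si in seq_len(nrow(plan))) {
    cond <- plan$condition[si]; tp <- plan$timepoint[si]
    truth_state <- logical(n)
    if (tp == axis$start_anchor) {
      truth_state <- base %in% c("PO", "OC")
    } else if (tp == axis$end_anchor) {
      truth_state <- base %in% c("PO", "CO")
    } else {
      # vectorized form of true_trajectory() at inner position j
      j <- match(tp, axis$inner)
      sub_here <- cond_sub[[cond]]
      truth_state <- (base == "PO") |
        (base == "NE" & j %in% ne_open_positions(K - 1L)) |
        (base == "OC" & j < sub_here) |
        (base == "CO" & j >= sub_here)
    }
    flip <- runif(n) < config$flicker_noise
    open <- xor(truth_state, flip)
    gr <- make_intervals(coords$chrom[open], coords$start[open],
                         coords$end[open],
                         score = round(runif(sum(open), 3, 10), 3),
                         name = sprintf("%s_%s_p%d", cond, tp,
                                        seq_len(sum(open))))
    peak_sets[[si]] <- peak_set(gr, condition = cond, timepoint = tp)
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(peak_sets, function(p) {
      f <- file.path(out_dir, sprintf("atac_%s_%s.narrowPeak",
                                      p$key$condition, p$key$timepoint))
      write_peaks(p, f, format = "narrowpeak")
      f
    }, "")
    tf <- file.path(out_dir, "truth_accessibility.tsv")
    write.table(truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, tf)
  }
  list(peak_sets = peak_sets, truth = truth, files = files, config = config)
}

# draw n values from N(mean, sd) conditioned on exceeding `gate` (planted
# effects must clear the significance gate to be recoverable by design)
rtrunc_above <- function(n, mean, sd, gate) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= gate)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# null-like draw conditioned on NOT crossing the call gate
r_null_guarded <- function(n, sd, lfc_gate, p_gate) {
  lfc <- rnorm(n, 0, sd); p <- runif(n)
  while (any(bad <- abs(lfc) > lfc_gate & p < p_gate)) {
    lfc[bad] <- rnorm(sum(bad), 0, sd); p[bad] <- runif(sum(bad))
  }
  list(lfc = lfc, p = p)
}

plant_anchor_expr <- function(bins, fc = 2) {
  n <- length(bins)
  mef <- runif(n, 5, 50)
  esc <- numeric(n)
  u <- runif(n, 1.2, 3)
  hi <- bins == "ESC_high"; lo <- bins == "MEF_high"; mid <- !hi & !lo
  esc[hi] <- (mef[hi] + 1) * fc * u[hi] - 1
  esc[lo] <- pmax(0, (mef[lo] + 1) / (fc * u[lo]) - 1)
  esc[mid] <- (mef[mid] + 1) * runif(sum(mid), 0.6, 1.6) - 1
  data.frame(expr_mef = round(mef, 3), expr_esc = round(esc, 3))
}

#' Simulate cross-system differential-expression tables
#'
#' Plants genes in every named category (common/pairwise/specific up and
#' down) across the treatment systems (all conditions except the first,
#' which is the control), with truncated-normal effects above the call gate
#' and tiny p-values at one active timepoint; null genes draw
#' `log2fc ~ N(0, null_lfc_sd)` and `p ~ U(0,1)` everywhere. Planted genes'
#' inactive cells are sampled from the null conditioned on non-significance
#' so that planted categories are exactly recoverable at zero noise. Anchor
#' expression respects each gene's planted bin.
#'
#' @param config validated [default_sim_config()].
#' @param out_dir optional directory: writes `de_<system>.tsv` per system,
#'   `ref_expression.tsv`, `truth_de.tsv`.
#' @return list with `records` (all systems), `ref_expr`, `truth`, `files`.
#' @export
simulate_de <- function(config, out_dir = NULL) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "expression"))
  axis <- config$axis_obj
  systems <- config$conditions[-1L]
  tps <- axis$inner
  g <- config$de$genes
  pairs <- if (length(systems) >= 2L) utils::combn(systems, 2L,
                                                   simplify = FALSE) else list()

  plant <- list()
  add <- function(class, members, count) {
    if (count > 0) {
      plant[[length(plant) + 1L]] <<- data.frame(
        class = class, members = paste(sort(members), collapse = "&"),
        idx = seq_len(count), stringsAsFactors = FALSE)
    }
  }
  add("common_up", systems, g[["common_up"]])
  add("common_down", systems, g[["common_down"]])
  for (s in systems) {
    add("specific_up", s, g[["specific_up"]])
    add("specific_down", s, g[["specific_down"]])
  }
  for (p in pairs) {
    add("pair_up", p, g[["pair_up"]])
    add("pair_down", p, g[["pair_down"]])
  }
  planted <- if (length(plant) > 0L) do.call(rbind, plant) else
    data.frame(class = character(), members = character(), idx = integer())
  n_planted <- nrow(planted)
  n_null <- g[["null"]]
  genes <- sprintf("G%05d", seq_len(n_planted + n_null))
  planted$gene <- genes[seq_len(n_planted)]

  bins <- sample(c("ESC_high", "MEF_high", "neutral"),
                 n_planted + n_null, replace = TRUE)
  active_tp <- sample(tps, n_planted + n_null, replace = TRUE)

  rows <- vector("list", 0L)
  de <- config$de
  for (s in systems) {
    lfc <- matrix(0, nrow = length(genes), ncol = length(tps))
    pv <- matrix(1, nrow = length(genes), ncol = length(tps))
    # nulls everywhere by default
    nl <- length(genes) * length(tps)
    lfc[] <- rnorm(nl, 0, de$null_lfc_sd)
    pv[] <- runif(nl)
    if (n_planted > 0L) {
      in_sys <- vapply(strsplit(planted$members, "&", fixed = TRUE),
                       function(m) s %in% m, TRUE)
      # guard planted genes' inactive cells against spurious calls
      guard_rows <- seq_len(n_planted)
      gr <- r_null_guarded(n_planted * length(tps), de$null_lfc_sd,
                           de$lfc_gate, de$p_gate)
      lfc[guard_rows, ] <- gr$lfc
      pv[guard_rows, ] <- gr$p
      act <- which(in_sys)
      if (length(act) > 0L) {
        j <- match(active_tp[act], tps)
        sign <- ifelse(grepl("down", planted$class[act]), -1, 1)
        lfc[cbind(act, j)] <- sign * rtrunc_above(length(act), de$lfc_mean,
                                                  de$lfc_sd, de$lfc_gate)
        pv[cbind(act, j)] <- runif(length(act), 0, de$p_planted_max)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rep(genes, times = length(tps)),
      system = s,
      timepoint = rep(tps, each = length(genes)),
      log2fc = round(as.vector(lfc), 4),
      pvalue = signif(as.vector(pv), 6),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)

  ref_expr <- cbind(data.frame(gene = genes, stringsAsFactors = FALSE),
                    plant_anchor_expr(bins))

  truth <- data.frame(
    gene = genes,
    class = c(planted$class, rep("none", n_null)),
    members = c(planted$members, rep("", n_null)),
    anchor_bin = bins,
    active_timepoint = active_tp,
    stringsAsFactors = FALSE)
  truth$category <- ifelse(
    truth$class %in% c("pair_up", "pair_down", "specific_up", "specific_down"),
    sprintf("%s(%s)", truth$class, truth$members), truth$class)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(systems, function(s) {
      f <- file.path(out_dir, sprintf("de_%s.tsv", s))
      write.table(records[records$system == s, ], f, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      f
    }, "")
    f2 <- file.path(out_dir, "ref_expression.tsv")
    write.table(ref_expr, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    f3 <- file.path(out_dir, "truth_de.tsv")
    write.table(truth, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f2, f3)
  }
  list(records = records, ref_expr = ref_expr, truth = truth, files = files,
       config = config)
}

#' Simulate a TSS / gene-model table on the synthetic genome
#'
#' Genes are placed uniformly with alternating strand; gene bodies extend
#' downstream of the TSS.
#'
#' @param config validated [default_sim_config()].
#' @param genes optional gene identifiers (defaults to the DE gene ids).
#' @param out_dir optional directory: writes `tss_table.tsv`.
#' @return list with `tss` data.frame and `files`.
#' @export
simulate_tss <- function(config, genes = NULL, out_dir = NULL) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "tss"))
  if (is.null(genes)) {
    n <- config$tss$n_genes
    genes <- sprintf("G%05d", seq_len(n))
  }
  n <- length(genes)
  chrom <- sample(names(config$genome), n, replace = TRUE,
                  prob = config$genome / sum(config$genome))
  tss <- floor(runif(n, 1e4, config$genome[chrom] - 1e5))
  df <- data.frame(gene = genes, chrom = chrom, tss = tss,
                   strand = rep_len(c("+", "-"), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$tss), , drop = FALSE]
  rownames(df) <- NULL
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(out_dir, "tss_table.tsv")
    write.table(df, files, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tss = df, files = files)
}

#' Simulate binding peaks at class-specific rates
#'
#' Every accessibility region whose shared base class has a configured rate
#' independently hosts one binding peak (covering the region) with that
#' probability.
#'
#' @param config validated [default_sim_config()].
#' @param truth accessibility truth (from [simulate_accessibility()]).
#' @param out_dir optional directory: writes `binding.narrowPeak` and
#'   `truth_binding.tsv`.
#' @return list with `peaks` ([peak_set()]), `truth` (per-peak planted
#'   class), `files`.
#' @export
simulate_binding <- function(config, truth, out_dir = NULL) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "binding"))
  rates <- config$binding$rates
  host <- rep(FALSE, nrow(truth))
  for (cl in names(rates)) {
    idx <- which(truth$base == cl)
    host[idx] <- runif(length(idx)) < rates[[cl]]
  }
  sel <- truth[host, , drop = FALSE]
  gr <- make_intervals(sel$chrom, sel$start, sel$end,
                       score = round(runif(nrow(sel), 3, 10), 3),
                       name = sprintf("bind_p%d", seq_len(nrow(sel))))
  peaks <- peak_set(gr, condition = "binding", timepoint = "D3")
  btruth <- data.frame(chrom = sel$chrom, start = sel$start, end = sel$end,
                       class = sel$base, stringsAsFactors = FALSE)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "binding.narrowPeak")
    write_peaks(peaks, f1, format = "narrowpeak")
    f2 <- file.path(out_dir, "truth_binding.tsv")
    write.table(btruth, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(f1, f2)
  }
  list(peaks = peaks, truth = btruth, files = files)
}

#' Run every simulation stage
#'
#' @param config validated [default_sim_config()] (or raw list).
#' @param out_dir optional output directory for all stage files.
#' @return list with `accessibility`, `de`, `tss`, `binding` stage results.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  config <- validate_sim_config(config)
  acc <- simulate_accessibility(config, out_dir)
  de <- simulate_de(config, out_dir)
  tss <- simulate_tss(config, genes = de$truth$gene, out_dir = out_dir)
  bind <- simulate_binding(config, acc$truth, out_dir)
  list(accessibility = acc, de = de, tss = tss, binding = bind,
       config = config)
}
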
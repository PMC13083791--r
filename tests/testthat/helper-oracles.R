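# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: interval questions are answered on per-base boolean
# coverage arrays, trajectory and direction questions by literal scans of
# the rules, hypergeometric p by exhaustive draw enumeration.

# ---- per-base coverage oracles (0-based half-open data.frames) ------------

ob_coverage <- function(df, genome) {
  cov <- lapply(genome, function(len) logical(len))
  for (i in seq_len(nrow(df))) {
    cov[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  cov
}

# maximal runs of TRUE, as 0-based half-open intervals (equals the
# bookended-merge result)
ob_runs <- function(cov) {
  out <- list()
  for (chrom in names(cov)) {
    r <- rle(cov[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                 end = ends[keep])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

ob_overlap_any <- function(qdf, sdf, genome) {
  scov <- ob_coverage(sdf, genome)
  vapply(seq_len(nrow(qdf)), function(i) {
    any(scov[[qdf$chrom[i]]][(qdf$start[i] + 1):qdf$end[i]])
  }, TRUE)
}

ob_subtract <- function(pdf, cdf, genome) {
  if (nrow(cdf) == 0L) return(pdf)
  hit <- ob_overlap_any(pdf, cdf, genome)
  pdf[!hit, , drop = FALSE]
}

random_interval_df <- function(n, genome) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample(1:500, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(genome[[chrom[i]]] - len[i], 1L) - 1L
  }, 1L)
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

df_from_gr <- function(gr) {
  intervals_to_df(gr)[, c("chrom", "start", "end")]
}

# ---- trajectory classifier oracle ----------------------------------------

# literal reading of the rule: base class from the anchors, then the
# earliest position t whose suffix (t..K) all equals the endpoint state
oracle_classify <- function(states) {
  m <- states[1L]; e <- states[length(states)]
  base <- if (m && e) "PO" else if (m && !e) "OC" else if (!m && e) "CO"
  else "NE"
  if (base %in% c("PO", "NE")) return(list(base = base, sub = NA_integer_))
  traj <- states[-1L]  # inner timepoints then the end anchor
  K <- length(traj)
  for (t in seq_len(K)) {
    if (all(traj[t:K] == e)) return(list(base = base, sub = t))
  }
  stop("unreachable: the final element always equals the endpoint")
}

# exact probability that independent per-call flips preserve the planted
# label, by enumeration of all flip patterns over the six determining calls
oracle_label_survival <- function(states, p) {
  truth_lab <- oracle_classify(states)
  n <- length(states)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    flip <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    obs <- xor(states, flip)
    lab <- oracle_classify(obs)
    if (identical(lab, truth_lab)) {
      total <- total + prod(ifelse(flip, p, 1 - p))
    }
  }
  total
}

# ---- cross-system truth-table oracle -------------------------------------

# independently coded: counts, written as a plain decision list
oracle_categorize <- function(directions, systems) {
  if (any(directions == "excluded")) return("discordant")
  n_up <- sum(directions == "up"); n_dn <- sum(directions == "down")
  n <- length(directions)
  if (n_up > 0 && n_dn > 0) return("discordant")
  if (n_up == n) return("common_up")
  if (n_dn == n) return("common_down")
  if (n_up == 1) return(sprintf("specific_up(%s)",
                                systems[directions == "up"]))
  if (n_dn == 1) return(sprintf("specific_down(%s)",
                                systems[directions == "down"]))
  if (n_up >= 2) return(sprintf("pair_up(%s)",
                                paste(sort(systems[directions == "up"]),
                                      collapse = "&")))
  if (n_dn >= 2) return(sprintf("pair_down(%s)",
                                paste(sort(systems[directions == "down"]),
                                      collapse = "&")))
  "none"
}

# ---- hypergeometric enumeration oracle -----------------------------------

# P(overlap >= k) by enumerating every possible draw of size n from the
# universe, with set_a fixed
oracle_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # universe items 1..K are the successes
  mean(hits >= k)
}

# ---- misc -----------------------------------------------------------------

# small ready-made state matrix: build peak sets from explicit open maps
toy_peak_sets <- function(open_map, intervals_df) {
  lapply(names(open_map), function(id) {
    parts <- strsplit(id, ":", fixed = TRUE)[[1L]]
    rows <- intervals_df[open_map[[id]], , drop = FALSE]
    peak_set(make_intervals(rows$chrom, rows$start, rows$end),
             condition = parts[1L], timepoint = parts[2L])
  })
}
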
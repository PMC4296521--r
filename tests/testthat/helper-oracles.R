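# Independent brute-force oracles, deliberately written from first
# principles (simple loops, no reuse of package internals) so they can
# cross-check the implementation.

# Exhaustive per-column fixation scan.
oracle_diagnostic_sites <- function(mat_a, mat_b, min_coverage = 2L) {
  bases <- c("A", "C", "G", "T")
  hits <- data.frame(position = integer(), state_a = character(),
                     state_b = character(), stringsAsFactors = FALSE)
  for (p in seq_len(ncol(mat_a))) {
    oa <- mat_a[, p][mat_a[, p] %in% bases]
    ob <- mat_b[, p][mat_b[, p] %in% bases]
    if (length(oa) < min_coverage || length(ob) < min_coverage) next
    if (length(unique(oa)) == 1L && length(unique(ob)) == 1L &&
        oa[1] != ob[1]) {
      hits <- rbind(hits, data.frame(position = p, state_a = oa[1],
                                     state_b = ob[1],
                                     stringsAsFactors = FALSE))
    }
  }
  hits
}

# Exhaustive per-offset degenerate-primer search (forward-strand pattern).
oracle_pattern_hits <- function(template, pattern, max_mismatches = 0L) {
  expand <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"),
                 V = c("A", "C", "G"))
  t <- strsplit(template, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  out <- data.frame(start = integer(), mismatches = integer())
  if (length(p) > length(t)) return(out)
  for (s in seq_len(length(t) - length(p) + 1L)) {
    mm <- 0L
    for (i in seq_along(p)) {
      tb <- t[s + i - 1L]
      ok <- tb %in% names(expand) &&
        length(intersect(expand[[p[i]]], expand[[tb]])) > 0L
      if (!ok) mm <- mm + 1L
    }
    if (mm <= max_mismatches) {
      out <- rbind(out, data.frame(start = s, mismatches = mm))
    }
  }
  out
}

# Brute-force pairwise percent extremes for barcode_gap checks.
oracle_gap_extremes <- function(seqs, groups) {
  pct <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
    floor(100 * sum(ca[keep] != cb[keep]) / sum(keep) * 10 + 0.5) / 10
  }
  n <- length(seqs)
  within <- between <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    d <- pct(seqs[i], seqs[j])
    if (groups[i] == groups[j]) within <- c(within, d)
    else between <- c(between, d)
  }
  list(max_within = if (length(within)) max(within) else NA_real_,
       min_between = min(between))
}

# Best single-threshold accuracy by exhaustive scan over all cut points
# and both polarities.
oracle_threshold_accuracy <- function(values, labels) {
  cuts <- sort(unique(values))
  cuts <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2,
            cuts[length(cuts)] + 1)
  best <- 0L
  for (thr in cuts) for (hi in unique(labels)) {
    pred <- ifelse(values > thr, hi, setdiff(unique(labels), hi))
    best <- max(best, sum(pred == labels))
  }
  best
}
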
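# Weighted morphometric segregation scores and hiatus testing.
#
# Two composite axes separate the cryptic species pair:
#   genitalic score: 0.6 * "U-B angle" + 0.2 * (B-A)/(C-B) + 0.2 * G/H
#   facies score:    0.15 * YL + 0.4 * F/P + 0.4 * T/V + 0.05 * W/D
# The U-B angle (between uncus and brachium in lateral view) is in radians;
# YL is 1 when the yellow neck line is continuous, 0 when broken into
# spots; the remaining symbols are linear distances in any consistent unit
# (only their ratios enter, so the scores are scale-free). The anatomical
# definitions of the distances are taken as given: measurements arrive as a
# CSV contract, the weights as published constants.

.check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("validation error: ", what, " must be positive and finite")
  }
}

#' Genitalic composite score
#'
#' @param ub_angle uncus-brachium angle in radians, in [0, pi].
#' @param A,B,C landmark distances entering (B-A)/(C-B); requires C > B.
#' @param G,H distances entering G/H.
#' @return 0.6*ub_angle + 0.2*(B-A)/(C-B) + 0.2*G/H (vectorized).
#' @export
genitalia_score <- function(ub_angle, A, B, C, G, H) {
  .check_positive(A, "A"); .check_positive(B, "B"); .check_positive(C, "C")
  .check_positive(G, "G"); .check_positive(H, "H")
  if (any(ub_angle < 0 | ub_angle > pi)) {
    stop("validation error: ub_angle must lie in [0, pi] radians")
  }
  if (any(C == B)) stop("degenerate measure: C equals B (zero denominator)")
  if (any(C < B)) stop("validation error: C must exceed B")
  0.6 * ub_angle + 0.2 * (B - A) / (C - B) + 0.2 * G / H
}

#' Facies composite score
#'
#' @param YL 1 if the yellow neck line is continuous, 0 if broken into
#'   spots.
#' @param F_,P,T_,V,W,D distances entering F/P, T/V and W/D (F and T are
#'   suffixed to avoid masking base R's F/T).
#' @return 0.15*YL + 0.4*F/P + 0.4*T/V + 0.05*W/D (vectorized).
#' @export
facies_score <- function(YL, F_, P, T_, V, W, D) {
  if (any(!YL %in% c(0, 1))) {
    stop("validation error: YL must be 0 or 1")
  }
  .check_positive(P, "P"); .check_positive(V, "V"); .check_positive(D, "D")
  if (any(!is.finite(F_) | F_ < 0) || any(!is.finite(T_) | T_ < 0) ||
      any(!is.finite(W) | W < 0)) {
    stop("validation error: F, T, W must be non-negative and finite")
  }
  0.15 * YL + 0.4 * F_ / P + 0.4 * T_ / V + 0.05 * W / D
}

MORPHO_COLUMNS <- c("ub_angle_rad", "A", "B", "C", "G", "H",
                    "YL", "F", "P", "T", "V", "W", "D")

#' Read a morphometric measurement table from CSV
#'
#' Expected columns: specimen_id, ub_angle_rad, A, B, C, G, H, YL, F, P, T,
#' V, W, D, optional true_label. Either measure block (genitalia or facies)
#' may be absent or NA per specimen; composite scores are computed where
#' the block is complete. Angles may be supplied in degrees via
#' \code{angles = "degrees"}.
#'
#' @param path CSV path.
#' @param angles "radians" (default) or "degrees".
#' @return a \code{morpho_records} data frame with added g_score / f_score.
#' @export
read_morpho_csv <- function(path, angles = c("radians", "degrees")) {
  angles <- match.arg(angles)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(df)) stop("morphometrics CSV needs specimen_id")
  for (col in MORPHO_COLUMNS) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"true_label" %in% names(df)) df$true_label <- NA_character_
  if (angles == "degrees") df$ub_angle_rad <- df$ub_angle_rad * pi / 180
  morpho_scores(df)
}

#' Add composite scores to a morphometric table
#'
#' @param df data frame with the \code{MORPHO_COLUMNS} measures.
#' @return same data frame with g_score and f_score columns filled where
#'   the corresponding measure block is complete; errors if no specimen has
#'   any complete block.
#' @export
morpho_scores <- function(df) {
  gen_ok <- stats::complete.cases(df[, c("ub_angle_rad", "A", "B", "C",
                                         "G", "H")])
  fac_ok <- stats::complete.cases(df[, c("YL", "F", "P", "T", "V", "W", "D")])
  if (!any(gen_ok | fac_ok)) {
    stop("no specimen has a complete genitalia or facies measure block")
  }
  df$g_score <- NA_real_
  df$f_score <- NA_real_
  if (any(gen_ok)) {
    df$g_score[gen_ok] <- genitalia_score(df$ub_angle_rad[gen_ok],
                                          df$A[gen_ok], df$B[gen_ok],
                                          df$C[gen_ok], df$G[gen_ok],
                                          df$H[gen_ok])
  }
  if (any(fac_ok)) {
    df$f_score[fac_ok] <- facies_score(df$YL[fac_ok], df$F[fac_ok],
                                       df$P[fac_ok], df$T[fac_ok],
                                       df$V[fac_ok], df$W[fac_ok],
                                       df$D[fac_ok])
  }
  class(df) <- unique(c("morpho_records", class(df)))
  df
}

#' Test for complete segregation with a hiatus on one axis
#'
#' Computes the per-group range of the chosen axis, whether the ranges are
#' disjoint (a hiatus), the gap width, and which specimens the midpoint
#' rule misassigns. The classification threshold is the midpoint of the
#' inner range edges (deterministic and scale-free).
#'
#' @param records a \code{morpho_records} data frame with true_label set.
#' @param axis column to test: "g_score", "f_score", or any raw measure
#'   name.
#' @return a \code{hiatus_report} list: axis, ranges (2x2 matrix), groups,
#'   separated, gap_width, threshold, misassigned_ids.
#' @export
hiatus_test <- function(records, axis = "g_score") {
  if (!axis %in% names(records)) stop("unknown axis: ", axis)
  keep <- !is.na(records[[axis]]) & !is.na(records$true_label)
  df <- records[keep, ]
  groups <- sort(unique(df$true_label))
  if (length(groups) != 2L) {
    stop("need exactly 2 labeled groups, got ", length(groups))
  }
  v <- split(df[[axis]], df$true_label)
  means <- vapply(v, mean, numeric(1))
  lo <- names(which.min(means)); hi <- setdiff(groups, lo)
  ranges <- rbind(range(v[[lo]]), range(v[[hi]]))
  dimnames(ranges) <- list(c(lo, hi), c("min", "max"))
  inner_low <- max(v[[lo]]); inner_high <- min(v[[hi]])
  separated <- inner_low < inner_high
  gap_width <- max(0, inner_high - inner_low)
  threshold <- (inner_low + inner_high) / 2
  predicted <- ifelse(df[[axis]] > threshold, hi, lo)
  mis <- df$specimen_id[predicted != df$true_label]
  structure(
    list(axis = axis, groups = c(low = lo, high = hi), ranges = ranges,
         separated = separated, gap_width = gap_width,
         threshold = threshold, misassigned_ids = mis),
    class = "hiatus_report"
  )
}

#' @export
print.hiatus_report <- function(x, ...) {
  cat(sprintf("hiatus on %s: %s (gap %.4g, threshold %.4g)\n", x$axis,
              if (x$separated) "separated" else "overlapping",
              x$gap_width, x$threshold))
  print(x$ranges)
  if (length(x$misassigned_ids)) {
    cat("misassigned:", paste(x$misassigned_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Best single-measure threshold classification accuracy
#'
#' Exhaustively scans thresholds (midpoints between adjacent distinct
#' values, in both polarity directions) on one raw measure or composite
#' score and reports the best achievable accuracy and the specimens
#' misclassified at that threshold.
#'
#' @param records a \code{morpho_records} data frame with true_label.
#' @param measure column name to threshold.
#' @return list(n_correct, n_total, misassigned_ids, threshold,
#'   high_group): values above the threshold are assigned to high_group.
#' @export
single_measure_accuracy <- function(records, measure) {
  if (!measure %in% names(records)) stop("unknown measure: ", measure)
  keep <- !is.na(records[[measure]]) & !is.na(records$true_label)
  df <- records[keep, ]
  groups <- sort(unique(df$true_label))
  if (length(groups) != 2L) stop("need exactly 2 labeled groups")
  if (any(table(df$true_label) < 2L)) {
    stop("need at least 2 records per group")
  }
  vals <- sort(unique(df[[measure]]))
  cuts <- c(vals[1] - 1, (vals[-1] + vals[-length(vals)]) / 2,
            vals[length(vals)] + 1)
  best <- NULL
  for (thr in cuts) {
    for (hi in groups) {
      lo <- setdiff(groups, hi)
      predicted <- ifelse(df[[measure]] > thr, hi, lo)
      n_correct <- sum(predicted == df$true_label)
      if (is.null(best) || n_correct > best$n_correct) {
        best <- list(n_correct = n_correct, n_total = nrow(df),
                     misassigned_ids =
                       df$specimen_id[predicted != df$true_label],
                     threshold = thr, high_group = hi)
      }
    }
  }
  best
}
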
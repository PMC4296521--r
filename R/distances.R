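# Pairwise p-distances with pairwise deletion, haplotype collapsing,
# barcode-gap analysis and neighbor-joining dendrograms.
#
# The distance convention follows the barcoding literature: uncorrected
# p-distance (Hamming fraction) over the positions unambiguous in BOTH
# sequences of a pair; ambiguity codes and gaps count as missing. Printed
# percentages are rounded half-up to one decimal, which reproduces the
# usual percent <-> base-pair correspondences on a 658-bp frame
# (23 bp -> 3.5%, 14 bp -> 2.1%, 1 bp -> 0.2%).

UNAMBIG <- c("A", "C", "G", "T")

#' Round half-up to a fixed number of decimals
#'
#' Base R's round() uses banker's rounding; barcode percentages are
#' conventionally rounded half away from zero.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_row_chars <- function(row) {
  if (is.character(row) && length(row) == 1L) seq_chars(row) else row
}

#' Uncorrected pairwise distance with pairwise deletion
#'
#' @param row_a,row_b anchored rows (length-L strings or character vectors)
#'   from the same reference frame.
#' @return a \code{pairwise_distance} list: \code{n_diff},
#'   \code{n_compared}, \code{fraction}, \code{percent_1dp}.
#' @export
p_distance <- function(row_a, row_b) {
  a <- as_row_chars(row_a)
  b <- as_row_chars(row_b)
  if (length(a) != length(b)) {
    stop("rows differ in length (", length(a), " vs ", length(b),
         "); anchor both to the same frame first")
  }
  mask <- a %in% UNAMBIG & b %in% UNAMBIG
  n_compared <- sum(mask)
  if (n_compared == 0L) {
    stop("undefined distance: no positions compared (disjoint coverage)")
  }
  n_diff <- sum(a[mask] != b[mask])
  fraction <- n_diff / n_compared
  structure(
    list(n_diff = n_diff, n_compared = n_compared, fraction = fraction,
         percent_1dp = round_half_up(100 * fraction, 1L)),
    class = "pairwise_distance"
  )
}

#' All pairwise distances of an alignment
#'
#' @param aln a \code{barcode_alignment}.
#' @return a \code{barcode_dist} list of matrices: \code{n_diff},
#'   \code{n_compared}, \code{fraction}, \code{percent} (all symmetric,
#'   zero diagonal) plus \code{ids}.
#' @export
distance_matrix <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 rows")
  ids <- rownames(aln)
  m <- unclass(aln)
  # per-base indicator products give all pairwise match / coverage counts
  valid <- (m %in% UNAMBIG)
  dim(valid) <- dim(m)
  valid <- valid * 1
  n_comp <- valid %*% t(valid)
  matches <- matrix(0, n, n)
  for (base in UNAMBIG) {
    ind <- (m == base) * 1
    matches <- matches + ind %*% t(ind)
  }
  n_diff <- n_comp - matches
  off_diag <- row(n_comp) != col(n_comp)
  if (any(n_comp[off_diag] == 0)) {
    bad <- which(n_comp == 0 & off_diag, arr.ind = TRUE)[1, ]
    stop("pair (", ids[bad[1]], ", ", ids[bad[2]],
         "): undefined distance: no positions compared (disjoint coverage)")
  }
  fraction <- n_diff / n_comp
  diag(fraction) <- 0
  percent <- round_half_up(100 * fraction, 1L)
  diag(n_diff) <- 0
  dimnames(n_diff) <- dimnames(n_comp) <- dimnames(fraction) <-
    dimnames(percent) <- list(ids, ids)
  structure(list(ids = ids, n_diff = n_diff, n_compared = n_comp,
                 fraction = fraction, percent = percent),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat("barcode_dist:", length(x$ids), "specimens; p-distance range ",
      sprintf("%.4f..%.4f\n", min(x$fraction[upper.tri(x$fraction)]),
              max(x$fraction[upper.tri(x$fraction)])))
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm a \code{barcode_dist}.
#' @param path output path.
#' @param strict use strict 10-character padded names instead of the default
#'   relaxed tab-separated names.
#' @export
write_phylip <- function(dm, path, strict = FALSE) {
  n <- length(dm$ids)
  lines <- character(n + 1L)
  lines[1] <- sprintf("%5d", n)
  for (i in seq_len(n)) {
    vals <- sprintf("%.6f", dm$fraction[i, ])
    name <- if (strict) sprintf("%-10s", substr(dm$ids[i], 1L, 10L))
            else dm$ids[i]
    sep <- if (strict) " " else "\t"
    lines[i + 1L] <- paste(c(name, vals), collapse = sep)
  }
  writeLines(lines, path)
  invisible(path)
}

# Can two rows belong to the same haplotype? Identical at every position
# unambiguous in both.
.compatible <- function(a, b) {
  mask <- a %in% UNAMBIG & b %in% UNAMBIG
  all(a[mask] == b[mask])
}

#' Collapse aligned barcodes into haplotypes
#'
#' Rows with at least \code{min_length} unambiguous positions are eligible
#' (default 658: the haplotype census in this analysis is over full-length
#' barcodes only). Eligible rows are partitioned into classes identical at
#' every mutually compared position; each class's representative is the
#' member with fewest missing positions (ties by lexicographic id).
#'
#' @param aln a \code{barcode_alignment}.
#' @param min_length minimum number of unambiguous positions for
#'   eligibility.
#' @return a \code{haplotype_table} data frame (haplotype, count,
#'   representative, members) sorted by descending count, with the
#'   representative sequences in \code{attr(, "sequences")}.
#' @export
collapse_haplotypes <- function(aln, min_length = 658L) {
  info <- row_informative(aln)
  eligible <- which(info >= min_length)
  classes <- list()  # each: list(members = ids, rows = list of char vecs)
  for (i in eligible) {
    row <- unclass(aln)[i, ]
    placed <- FALSE
    for (k in seq_along(classes)) {
      if (all(vapply(classes[[k]]$rows, .compatible, logical(1), b = row))) {
        classes[[k]]$members <- c(classes[[k]]$members, rownames(aln)[i])
        classes[[k]]$rows <- c(classes[[k]]$rows, list(row))
        classes[[k]]$info <- c(classes[[k]]$info, info[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      classes[[length(classes) + 1L]] <- list(
        members = rownames(aln)[i], rows = list(row), info = info[i])
    }
  }
  if (length(classes) == 0L) {
    out <- data.frame(haplotype = character(), count = integer(),
                      representative = character(), members = character(),
                      stringsAsFactors = FALSE)
    attr(out, "sequences") <- character()
    class(out) <- c("haplotype_table", "data.frame")
    return(out)
  }
  rep_id <- vapply(classes, function(cl) {
    best <- which(cl$info == max(cl$info))
    sort(cl$members[best])[1]
  }, character(1))
  rep_seq <- vapply(seq_along(classes), function(k) {
    cl <- classes[[k]]
    paste(cl$rows[[match(rep_id[k], cl$members)]], collapse = "")
  }, character(1))
  counts <- vapply(classes, function(cl) length(cl$members), integer(1))
  members <- vapply(classes, function(cl)
    paste(sort(cl$members), collapse = ","), character(1))
  ord <- order(-counts, rep_id)
  out <- data.frame(
    haplotype = paste0("H", seq_along(ord)),
    count = counts[ord],
    representative = rep_id[ord],
    members = members[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "sequences") <- rep_seq[ord]
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Barcode-gap analysis between labeled groups
#'
#' Computes the maximum within-group and minimum between-group pairwise
#' distances (on the 1-decimal percent scale the analysis reports) and the
#' gap (hiatus) between them.
#'
#' @param aln a \code{barcode_alignment}.
#' @param labels named character vector mapping specimen id -> group.
#' @param dm optional precomputed \code{barcode_dist} for \code{aln}.
#' @return a \code{barcode_gap_report} list: per-group \code{max_within},
#'   \code{min_between}, \code{gap}, \code{verdict} ("gap_present" or
#'   "no_gap"), the extreme pairs, and \code{flagged} when no within-group
#'   pair exists at all.
#' @export
barcode_gap <- function(aln, labels, dm = NULL) {
  ids <- rownames(aln)
  if (!all(ids %in% names(labels))) {
    stop("labels missing for: ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  }
  grp <- labels[ids]
  groups <- sort(unique(grp))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(dm)) dm <- distance_matrix(aln)
  pc <- dm$percent

  max_within <- stats::setNames(rep(NA_real_, length(groups)), groups)
  group_pair <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    members <- which(grp == g)
    if (length(members) >= 2L) {
      sub <- pc[members, members, drop = FALSE]
      ut <- upper.tri(sub)
      max_within[g] <- max(sub[ut])
      idx <- which(sub == max_within[g] & ut, arr.ind = TRUE)[1, ]
      group_pair[[g]] <- c(ids[members[idx[1]]], ids[members[idx[2]]])
    }
  }
  within_pair <- if (all(is.na(max_within))) NULL
                 else group_pair[[which.max(max_within)]]
  between_mask <- outer(grp, grp, "!=") & upper.tri(pc)
  min_between <- min(pc[between_mask])
  idx <- which(pc == min_between & between_mask, arr.ind = TRUE)[1, ]
  between_pair <- c(ids[idx[1]], ids[idx[2]])

  flagged <- all(is.na(max_within))
  overall_within <- if (flagged) NA_real_ else max(max_within, na.rm = TRUE)
  gap <- if (flagged) NA_real_ else min_between - overall_within
  verdict <- if (flagged) {
    if (min_between > 0) "gap_present" else "no_gap"
  } else if (gap > 0) "gap_present" else "no_gap"

  structure(
    list(groups = groups, max_within = max_within,
         overall_max_within = overall_within,
         min_between = min_between, gap = gap, verdict = verdict,
         max_within_pair = within_pair, min_between_pair = between_pair,
         flagged = flagged),
    class = "barcode_gap_report"
  )
}

#' @export
print.barcode_gap_report <- function(x, ...) {
  cat("barcode gap report\n")
  for (g in x$groups) {
    cat(sprintf("  max within %-12s: %s%%\n", g,
                ifelse(is.na(x$max_within[g]), "NA (single member)",
                       format(x$max_within[g]))))
  }
  cat(sprintf("  min between groups  : %s%% (%s vs %s)\n",
              format(x$min_between),
              x$min_between_pair[1], x$min_between_pair[2]))
  cat(sprintf("  gap                 : %s points -> %s%s\n",
              format(x$gap), x$verdict,
              if (x$flagged) " [flagged: no within-group pair]" else ""))
  invisible(x)
}

# Move negative NJ branch lengths onto the sister edge(s), one pass, then
# clamp whatever is still negative to zero (path lengths through the node
# are preserved where possible; a single pass avoids oscillation between
# two negative siblings).
.clamp_negative_edges <- function(tree) {
  for (e in which(tree$edge.length < 0)) {
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sisters) > 0) {
      tree$edge.length[sisters] <- tree$edge.length[sisters] +
        tree$edge.length[e] / length(sisters)
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining dendrogram from a distance matrix
#'
#' Standard NJ agglomeration (or the variance-weighted BioNJ variant) on the
#' p-distance fractions; negative branch lengths are clamped to zero with
#' the residual moved to the sister branch. Trees are plain illustrative
#' distance dendrograms, serializable as Newick via \code{ape::write.tree}.
#'
#' @param dm a \code{barcode_dist}.
#' @param variant "nj" (default) or "bionj".
#' @return an unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_dendrogram <- function(dm, variant = c("nj", "bionj")) {
  variant <- match.arg(variant)
  if (length(dm$ids) < 3L) stop("need at least 3 taxa for neighbor joining")
  d <- stats::as.dist(dm$fraction)
  tree <- if (variant == "bionj") ape::bionj(d) else ape::nj(d)
  .clamp_negative_edges(tree)
}
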
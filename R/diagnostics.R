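# Fixed diagnostic nucleotide discovery and character-based classification.
#
# A diagnostic site is a frame position fixed for one base X in group A and
# a different base Y in group B: the "k X (not Y)" characters used to
# diagnose the two species. Discovery is a strict per-column fixation scan;
# classification of unknowns (full barcodes or 64-bp ID tags) is simple
# majority voting over the scorable sites, reported with the vote margin.

# Observations supporting fixation in one column. strict: only ACGT counts,
# ambiguity = missing. lenient: an ambiguity code is consistent if the fixed
# base is among its expansions, and then counts toward coverage.
.column_fixed_state <- function(col, ambiguity = c("strict", "lenient")) {
  ambiguity <- match.arg(ambiguity)
  plain <- col[col %in% UNAMBIG]
  if (length(plain) == 0L) return(NULL)
  state <- unique(plain)
  if (length(state) != 1L) return(NULL)
  coverage <- length(plain)
  if (ambiguity == "lenient") {
    amb <- col[!(col %in% UNAMBIG) & col != "N" & col != "-"]
    consistent <- vapply(amb, function(a) state %in% iupac_expand(a),
                         logical(1))
    if (length(amb) > 0L && !all(consistent)) return(NULL)
    coverage <- coverage + sum(consistent)
  }
  list(state = state, coverage = coverage)
}

#' Find fixed diagnostic positions between two groups
#'
#' Returns the frame positions where every non-missing observation in group
#' A is one base X, every non-missing observation in group B is a different
#' base Y, and both groups have at least \code{min_coverage} supporting
#' observations.
#'
#' @param aln_a,aln_b \code{barcode_alignment} matrices (or plain character
#'   matrices) of the two groups, on the same frame.
#' @param min_coverage minimum non-missing observations per group at a site
#'   (default 2, so a single read cannot assert fixation).
#' @param ambiguity "strict" treats ambiguity codes as missing; "lenient"
#'   accepts an ambiguity code whose expansion contains the fixed base.
#' @return a \code{diagnostic_sites} data frame: position, state_a, state_b,
#'   coverage_a, coverage_b, sorted by position.
#' @export
find_diagnostic_sites <- function(aln_a, aln_b, min_coverage = 2L,
                                  ambiguity = c("strict", "lenient")) {
  ambiguity <- match.arg(ambiguity)
  if (nrow(aln_a) == 0L || nrow(aln_b) == 0L) stop("empty group")
  if (ncol(aln_a) != ncol(aln_b)) stop("groups are not on the same frame")
  ma <- unclass(aln_a); mb <- unclass(aln_b)
  out <- list()
  for (p in seq_len(ncol(ma))) {
    fa <- .column_fixed_state(ma[, p], ambiguity)
    if (is.null(fa) || fa$coverage < min_coverage) next
    fb <- .column_fixed_state(mb[, p], ambiguity)
    if (is.null(fb) || fb$coverage < min_coverage) next
    if (fa$state == fb$state) next
    out[[length(out) + 1L]] <- data.frame(
      position = p, state_a = fa$state, state_b = fb$state,
      coverage_a = fa$coverage, coverage_b = fb$coverage,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out)
           else data.frame(position = integer(), state_a = character(),
                           state_b = character(), coverage_a = integer(),
                           coverage_b = integer(), stringsAsFactors = FALSE)
  class(sites) <- c("diagnostic_sites", "data.frame")
  sites
}

#' Render diagnostic sites in "k X (not Y)" form
#'
#' @param sites a \code{diagnostic_sites} data frame.
#' @return a single comma-separated string, in position order; group A
#'   (the focal taxon) supplies X.
#' @export
format_sites <- function(sites) {
  if (nrow(sites) == 0L) return("")
  sites <- sites[order(sites$position), ]
  paste(sprintf("%d %s (not %s)", sites$position, sites$state_a,
                sites$state_b), collapse = ", ")
}

#' Read a diagnostic-site table from TSV
#'
#' Expects columns position, then the two per-group state columns (any
#' names, e.g. state_rumiko / state_cresphontes), optionally coverages.
#'
#' @param path TSV path.
#' @return a \code{diagnostic_sites} data frame (states mapped to state_a /
#'   state_b in column order).
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"position" %in% names(df) || ncol(df) < 3L) {
    stop("site table needs a 'position' column and two state columns")
  }
  state_cols <- setdiff(names(df), c("position", "coverage_a", "coverage_b"))
  out <- data.frame(
    position = as.integer(df$position),
    state_a = toupper(df[[state_cols[1]]]),
    state_b = toupper(df[[state_cols[2]]]),
    coverage_a = if ("coverage_a" %in% names(df)) df$coverage_a else NA_integer_,
    coverage_b = if ("coverage_b" %in% names(df)) df$coverage_b else NA_integer_,
    stringsAsFactors = FALSE)
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

#' The packaged 17-position diagnostic-site table
#'
#' The published "k X (not Y)" list separating H. rumiko (state_a) from
#' H. cresphontes (state_b) on the 658-bp frame.
#'
#' @return a \code{diagnostic_sites} data frame with 17 rows.
#' @export
published_sites <- function() {
  read_sites_tsv(system.file("extdata", "diagnostic_sites.tsv",
                             package = "barcodegap", mustWork = TRUE))
}

#' Classify one anchored row by diagnostic sites
#'
#' Each scorable site votes: the row's base equal to X votes for group A,
#' equal to Y for group B, any other unambiguous base for "other"; missing
#' or ambiguous bases are unscorable. The call is the majority with margin
#' at least 1, "ambiguous" on a tie, "unscorable" with no scorable site.
#'
#' @param row anchored row (string or character vector) on the sites' frame.
#' @param sites a \code{diagnostic_sites} data frame.
#' @param specimen_id optional id carried into the result.
#' @return a \code{site_classification} list: votes_a, votes_b, votes_other,
#'   n_scorable, call, margin.
#' @export
classify_by_sites <- function(row, sites, specimen_id = NA_character_) {
  if (nrow(sites) == 0L) stop("no diagnostic sites supplied")
  chars <- as_row_chars(row)
  if (max(sites$position) > length(chars)) {
    stop("row shorter than the largest site position")
  }
  obs <- chars[sites$position]
  scorable <- obs %in% UNAMBIG
  votes_a <- sum(scorable & obs == sites$state_a)
  votes_b <- sum(scorable & obs == sites$state_b)
  votes_other <- sum(scorable) - votes_a - votes_b
  call <- if (!any(scorable)) "unscorable"
          else if (votes_a > votes_b) "group_a"
          else if (votes_b > votes_a) "group_b"
          else "ambiguous"
  structure(
    list(specimen_id = specimen_id, votes_a = votes_a, votes_b = votes_b,
         votes_other = votes_other, n_scorable = sum(scorable),
         call = call, margin = abs(votes_a - votes_b)),
    class = "site_classification"
  )
}

#' Classify every row of an alignment by diagnostic sites
#'
#' @param aln a \code{barcode_alignment}.
#' @param sites a \code{diagnostic_sites} data frame.
#' @return data frame with one row per specimen: specimen_id, votes_a,
#'   votes_b, votes_other, n_scorable, call, margin.
#' @export
classify_alignment <- function(aln, sites) {
  res <- lapply(seq_len(nrow(aln)), function(i) {
    cl <- classify_by_sites(unclass(aln)[i, ], sites, rownames(aln)[i])
    data.frame(specimen_id = cl$specimen_id, votes_a = cl$votes_a,
               votes_b = cl$votes_b, votes_other = cl$votes_other,
               n_scorable = cl$n_scorable, call = cl$call,
               margin = cl$margin, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Most diagnostic window of the frame
#'
#' Finds the window of \code{window_length} frame positions containing the
#' most fixed differences between the two groups -- the criterion used to
#' place a mini-barcode ("ID tag") assay for degraded specimens.
#'
#' @param aln_a,aln_b the two groups' alignments.
#' @param window_length window width in frame positions.
#' @param min_coverage,ambiguity passed to
#'   \code{\link{find_diagnostic_sites}}.
#' @return list(start, end, n_fixed_differences); ties broken by smallest
#'   start.
#' @export
select_diagnostic_region <- function(aln_a, aln_b, window_length,
                                     min_coverage = 2L,
                                     ambiguity = c("strict", "lenient")) {
  L <- ncol(aln_a)
  if (window_length > L) stop("window_length ", window_length,
                              " exceeds frame length ", L)
  sites <- find_diagnostic_sites(aln_a, aln_b, min_coverage,
                                 match.arg(ambiguity))
  is_site <- integer(L)
  is_site[sites$position] <- 1L
  csum <- c(0L, cumsum(is_site))
  starts <- seq_len(L - window_length + 1L)
  counts <- csum[starts + window_length] - csum[starts]
  best <- which.max(counts)  # first maximum = smallest start
  list(start = starts[best], end = starts[best] + window_length - 1L,
       n_fixed_differences = counts[best])
}
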
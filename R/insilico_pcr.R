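# In-silico PCR with IUPAC-degenerate primers on barcode templates.
#
# Primers are stored 5'->3' as printed; reverse primers are
# reverse-complemented internally and all coordinates are reported 1-based
# on the template's forward strand. A hit requires the full primer length
# inside the template (templates here are barcode sequences, not genomic
# context, so partial 3' annealing is not modeled). Primers carrying a
# sequencing tail (e.g. M13 tails on LepF/LepR) declare the tail length in
# a tail5 annotation; only the 3' gene-specific portion is matched.

#' Construct a primer
#'
#' @param name primer name.
#' @param orientation "forward" or "reverse".
#' @param sequence 5'->3' IUPAC string (degenerate codes allowed).
#' @param tail5 number of 5' bases that are a universal sequencing tail and
#'   excluded from template matching (default 0).
#' @return a \code{primer} list.
#' @export
primer <- function(name, orientation = c("forward", "reverse"), sequence,
                   tail5 = 0L) {
  orientation <- match.arg(orientation)
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("primer '", name, "': empty sequence")
  bad <- first_invalid_char(chars)
  if (bad > 0L || any(chars == "-")) {
    stop("primer '", name, "': non-IUPAC character at offset ",
         if (bad > 0L) bad else which(chars == "-")[1])
  }
  if (tail5 >= length(chars)) stop("primer '", name, "': tail5 leaves no bases")
  structure(list(name = name, orientation = orientation,
                 sequence = paste(chars, collapse = ""),
                 tail5 = as.integer(tail5)),
            class = "primer")
}

#' Read a primer table from TSV
#'
#' Columns: name, orientation, sequence, optional tail5.
#'
#' @param path TSV path.
#' @return named list of \code{primer} objects.
#' @export
read_primers_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "orientation", "sequence")
  if (!all(needed %in% names(df))) {
    stop("primer table needs columns: ", paste(needed, collapse = ", "))
  }
  tail5 <- if ("tail5" %in% names(df)) df$tail5 else rep(0L, nrow(df))
  ps <- lapply(seq_len(nrow(df)), function(i)
    primer(df$name[i], df$orientation[i], df$sequence[i], tail5[i]))
  stats::setNames(ps, df$name)
}

#' The packaged primer set
#'
#' All primers printed for this barcoding protocol: the universal
#' tailed pair (LepF/LepR), the two- and four-segment Heraclides-specific
#' pairs, and the swtl-ID1F/swtl-ID1R ID-tag pair.
#'
#' @return named list of \code{primer} objects.
#' @export
published_primers <- function() {
  read_primers_tsv(system.file("extdata", "primers.tsv",
                               package = "barcodegap", mustWork = TRUE))
}

#' Do two IUPAC codes match?
#'
#' True iff the base sets of the two codes intersect. In strict mode an 'N'
#' in the template matches nothing: missing data cannot support a primer
#' site. In lenient mode template 'N' matches everything.
#'
#' @param primer_base IUPAC code from the primer.
#' @param template_base IUPAC code from the template.
#' @param template_n "strict" (default) or "lenient".
#' @return logical.
#' @export
iupac_match <- function(primer_base, template_base,
                        template_n = c("strict", "lenient")) {
  template_n <- match.arg(template_n)
  template_base <- toupper(template_base)
  if (template_base == "N") return(template_n == "lenient")
  if (template_base == "-") return(FALSE)
  length(intersect(iupac_expand(primer_base),
                   iupac_expand(template_base))) > 0L
}

# Vectorized position-wise mismatch count of a pattern at one template
# window; pattern and window are char vectors of equal length.
.window_mismatches <- function(pattern_sets, window, template_n) {
  mm <- 0L
  for (i in seq_along(window)) {
    b <- window[i]
    ok <- if (b == "N") template_n == "lenient"
          else if (b == "-") FALSE
          else any(pattern_sets[[i]] %in% IUPAC_SETS[[b]])
    if (!ok) mm <- mm + 1L
  }
  mm
}

#' Find primer binding sites on a template
#'
#' Forward primers are scanned as printed; reverse primers as their reverse
#' complement. All windows with at most \code{max_mismatches} mismatching
#' positions are reported on the forward strand.
#'
#' @param template ungapped template sequence (string).
#' @param p a \code{primer}.
#' @param max_mismatches tolerated mismatches (default 0).
#' @param template_n policy for 'N' in the template ("strict": never
#'   matches).
#' @return data frame (start, end, mismatches, strand) sorted by start;
#'   strand is "+" for forward primers, "-" for reverse primers (which
#'   anneal to the reverse strand).
#' @export
find_primer_sites <- function(template, p, max_mismatches = 0L,
                              template_n = c("strict", "lenient")) {
  template_n <- match.arg(template_n)
  stopifnot(inherits(p, "primer"))
  tchars <- seq_chars(template)
  eff <- substring(p$sequence, p$tail5 + 1L, nchar(p$sequence))
  pat <- if (p$orientation == "reverse") reverse_complement(eff) else eff
  pchars <- seq_chars(pat)
  np <- length(pchars); nt <- length(tchars)
  empty <- data.frame(start = integer(), end = integer(),
                      mismatches = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (np > nt) return(empty)
  pattern_sets <- IUPAC_SETS[pchars]
  hits <- list()
  for (s in seq_len(nt - np + 1L)) {
    mm <- .window_mismatches(pattern_sets, tchars[s:(s + np - 1L)],
                             template_n)
    if (mm <= max_mismatches) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = s + np - 1L, mismatches = mm,
        strand = if (p$orientation == "reverse") "-" else "+",
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) empty else do.call(rbind, hits)
}

#' In-silico PCR of a primer pair on a template
#'
#' Finds the unique shortest pairing of a forward-primer site upstream of a
#' reverse-primer site. The argument position fixes the role: \code{fwd} is
#' matched as printed, \code{rev} as its reverse complement, so swapping
#' the primers yields a no-amplification error.
#'
#' @param template ungapped template sequence.
#' @param fwd,rev \code{primer} objects for the forward and reverse role.
#' @param max_mismatches tolerated mismatches per primer (default 0;
#'   raising it models the fallback primers used when exact amplification
#'   fails).
#' @param template_n template-'N' policy, see \code{\link{iupac_match}}.
#' @return an \code{amplicon} list: primer names, fwd_start, fwd_end,
#'   rev_start, rev_end (1-based inclusive, forward strand),
#'   product_length, insert_length, mismatches.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatches = 0L,
                          template_n = c("strict", "lenient")) {
  template_n <- match.arg(template_n)
  fwd_role <- primer(fwd$name, "forward",
                     substring(fwd$sequence, fwd$tail5 + 1L), 0L)
  rev_role <- primer(rev$name, "reverse",
                     substring(rev$sequence, rev$tail5 + 1L), 0L)
  fhits <- find_primer_sites(template, fwd_role, max_mismatches, template_n)
  rhits <- find_primer_sites(template, rev_role, max_mismatches, template_n)
  if (nrow(fhits) == 0L) {
    stop("no amplification: forward primer '", fwd$name,
         "' not found on template")
  }
  if (nrow(rhits) == 0L) {
    stop("no amplification: reverse primer '", rev$name,
         "' not found on template")
  }
  pairings <- list()
  for (i in seq_len(nrow(fhits))) {
    for (j in seq_len(nrow(rhits))) {
      if (fhits$end[i] < rhits$start[j]) {
        pairings[[length(pairings) + 1L]] <- c(i = i, j = j,
          len = rhits$end[j] - fhits$start[i] + 1L)
      }
    }
  }
  if (length(pairings) == 0L) {
    stop("no amplification: no forward site upstream of a reverse site for ",
         fwd$name, "/", rev$name)
  }
  lens <- vapply(pairings, function(x) x[["len"]], numeric(1))
  shortest <- which(lens == min(lens))
  if (length(shortest) > 1L) {
    alts <- vapply(pairings[shortest], function(x)
      sprintf("fwd@%d/rev@%d", fhits$start[x[["i"]]],
              rhits$start[x[["j"]]]), character(1))
    stop("ambiguous amplification (", length(shortest),
         " shortest products of ", min(lens), " bp): ",
         paste(alts, collapse = ", "))
  }
  best <- pairings[[shortest]]
  i <- best[["i"]]; j <- best[["j"]]
  res <- list(
    primer_pair = c(forward = fwd$name, reverse = rev$name),
    fwd_start = fhits$start[i], fwd_end = fhits$end[i],
    rev_start = rhits$start[j], rev_end = rhits$end[j],
    product_length = rhits$end[j] - fhits$start[i] + 1L,
    insert_length = rhits$start[j] - fhits$end[i] - 1L,
    mismatches = c(fwd = fhits$mismatches[i], rev = rhits$mismatches[j])
  )
  class(res) <- "amplicon"
  res
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon %s/%s: %d..%d -> %d..%d, product %d bp, insert %d bp\n",
              x$primer_pair["forward"], x$primer_pair["reverse"],
              x$fwd_start, x$fwd_end, x$rev_start, x$rev_end,
              x$product_length, x$insert_length))
  invisible(x)
}

#' Extract the ID-tag insert amplified by a primer pair
#'
#' Runs \code{\link{in_silico_pcr}} and returns the primer-free insert as an
#' \code{id_tag} barcode record, with its frame offset recorded so it
#' anchors correctly (the insert's first base sits at template position
#' fwd_end + 1, i.e. anchor offset fwd_end when the template is itself
#' frame-anchored).
#'
#' @param template ungapped template on the reference frame.
#' @param fwd,rev the primer pair.
#' @param specimen_id id for the resulting record.
#' @param max_mismatches,template_n passed to \code{\link{in_silico_pcr}}.
#' @return a one-row \code{barcode_set} with completeness "id_tag" and the
#'   amplicon in \code{attr(, "amplicon")} / offset in
#'   \code{attr(, "frame_offset")}.
#' @export
extract_id_tag <- function(template, fwd, rev, specimen_id = "id_tag",
                           max_mismatches = 0L,
                           template_n = c("strict", "lenient")) {
  amp <- in_silico_pcr(template, fwd, rev, max_mismatches,
                       match.arg(template_n))
  insert <- substring(toupper(template), amp$fwd_end + 1L,
                      amp$rev_start - 1L)
  rec <- new_barcode_set(specimen_id, "", "", "id_tag", insert)
  attr(rec, "amplicon") <- amp
  attr(rec, "frame_offset") <- amp$fwd_end
  rec
}

#' Coverage of a reference frame by an amplification scheme
#'
#' Runs each primer pair on the reference sequence and reports the amplicon
#' intervals, the union coverage of frame positions, and the overlap or gap
#' between consecutive segments. Pairs that fail to amplify are flagged and
#' the rest still reported.
#'
#' @param frame a \code{reference_frame}.
#' @param pairs list of \code{list(fwd = primer, rev = primer)} pairs.
#' @param max_mismatches tolerated mismatches per primer.
#' @return a \code{scheme_coverage} list: \code{segments} data frame (pair,
#'   start, end, status), \code{covered} (count of covered positions),
#'   \code{coverage_fraction}, \code{junctions} data frame between
#'   consecutive successful segments (overlap > 0, gap > 0, or abutting).
#' @export
scheme_coverage <- function(frame, pairs, max_mismatches = 0L) {
  stopifnot(inherits(frame, "reference_frame"), length(pairs) >= 1L)
  segs <- lapply(pairs, function(pr) {
    amp <- tryCatch(in_silico_pcr(frame$reference_sequence, pr$fwd, pr$rev,
                                  max_mismatches),
                    error = function(e) conditionMessage(e))
    if (is.character(amp)) {
      data.frame(pair = paste(pr$fwd$name, pr$rev$name, sep = "/"),
                 start = NA_integer_, end = NA_integer_,
                 status = amp, stringsAsFactors = FALSE)
    } else {
      data.frame(pair = paste(pr$fwd$name, pr$rev$name, sep = "/"),
                 start = amp$fwd_start, end = amp$rev_end, status = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  segments <- do.call(rbind, segs)
  ok <- segments[!is.na(segments$start), , drop = FALSE]
  covered <- logical(frame$length)
  for (k in seq_len(nrow(ok))) covered[ok$start[k]:ok$end[k]] <- TRUE
  junctions <- data.frame(from = character(), to = character(),
                          overlap = integer(), gap = integer(),
                          stringsAsFactors = FALSE)
  if (nrow(ok) >= 2L) {
    ok <- ok[order(ok$start), ]
    for (k in seq_len(nrow(ok) - 1L)) {
      ov <- ok$end[k] - ok$start[k + 1L] + 1L
      junctions <- rbind(junctions, data.frame(
        from = ok$pair[k], to = ok$pair[k + 1L],
        overlap = max(0L, ov), gap = max(0L, -ov),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(segments = segments, covered = sum(covered),
                 coverage_fraction = sum(covered) / frame$length,
                 junctions = junctions),
            class = "scheme_coverage")
}
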
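# Reading, validation and reference-anchoring of COI barcode records.
#
# All coordinates exposed by this package are 1-based and inclusive, numbered
# on the ungapped reference barcode (positions 1..658 for the packaged
# holotype frame). Gaps ('-') on input are converted to the missing symbol
# 'N': butterfly COI barcodes align without insertions or deletions, so a
# gap can only mean a missing or unreadable base.

COMPLETENESS_LEVELS <- c("full", "partial", "id_tag")

# Minimum ungapped length for a record to be declared "full".
FULL_LENGTH_MIN <- 658L

new_barcode_set <- function(specimen_id, taxon_label, locality, completeness,
                            sequence) {
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    taxon_label = as.character(taxon_label),
    locality = as.character(locality),
    completeness = as.character(completeness),
    sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
  class(df) <- c("barcode_set", "data.frame")
  df
}

infer_completeness <- function(ungapped_len) {
  if (ungapped_len >= FULL_LENGTH_MIN) "full"
  else if (ungapped_len >= 100L) "partial"
  else "id_tag"
}

validate_barcode_set <- function(records) {
  for (i in seq_len(nrow(records))) {
    chars <- seq_chars(records$sequence[i])
    if (length(chars) == 0L) {
      stop("record '", records$specimen_id[i], "': empty sequence")
    }
    bad <- first_invalid_char(chars)
    if (bad > 0L) {
      stop("record '", records$specimen_id[i],
           "': non-IUPAC character '", chars[bad], "' at offset ", bad)
    }
    if (!records$completeness[i] %in% COMPLETENESS_LEVELS) {
      stop("record '", records$specimen_id[i], "': completeness must be one of ",
           paste(COMPLETENESS_LEVELS, collapse = ", "))
    }
    ungapped <- sum(chars != "-")
    if (records$completeness[i] == "full" && ungapped < FULL_LENGTH_MIN) {
      stop("record '", records$specimen_id[i], "': declared full but ungapped ",
           "length ", ungapped, " < ", FULL_LENGTH_MIN)
    }
  }
  invisible(records)
}

#' Read barcode records from a FASTA file
#'
#' Headers follow the convention
#' \code{specimen_id|taxon_label|locality|completeness}; missing fields
#' default to an empty taxon/locality and a completeness inferred from the
#' ungapped length (>= 658 full, >= 100 partial, else id_tag). Sequences are
#' upper-cased and validated against the IUPAC nucleotide alphabet plus '-'.
#'
#' @param path path to a FASTA file.
#' @return a \code{barcode_set} data frame with columns specimen_id,
#'   taxon_label, locality, completeness, sequence.
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw_lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(raw_lines)))
  if (length(nonblank) == 0L) {
    return(new_barcode_set(character(), character(), character(),
                           character(), character()))
  }
  if (!startsWith(trimws(raw_lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in ", path, ": line ", nonblank[1],
         " is not a header ('>')")
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  sequence <- toupper(as.character(seqs))

  specimen_id <- taxon_label <- locality <- completeness <-
    character(length(seqs))
  for (i in seq_along(seqs)) {
    fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    specimen_id[i] <- trimws(fields[1])
    taxon_label[i] <- if (length(fields) >= 2) trimws(fields[2]) else ""
    locality[i]    <- if (length(fields) >= 3) trimws(fields[3]) else ""
    chars <- seq_chars(sequence[i])
    declared <- if (length(fields) >= 4) trimws(fields[4]) else ""
    completeness[i] <- if (nzchar(declared)) declared
                       else infer_completeness(sum(chars != "-"))
  }
  records <- new_barcode_set(specimen_id, taxon_label, locality,
                             completeness, sequence)
  validate_barcode_set(records)
  records
}

#' Write barcode records to a FASTA file
#'
#' The inverse of \code{\link{read_barcode_fasta}}: a read of the written
#' file reproduces specimen ids, metadata and sequences exactly, in order.
#'
#' @param records a \code{barcode_set} data frame.
#' @param path output path.
#' @param width line width for wrapped sequence lines.
#' @export
write_barcode_fasta <- function(records, path, width = 70L) {
  validate_barcode_set(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- paste(records$specimen_id[i], records$taxon_label[i],
                    records$locality[i], records$completeness[i], sep = "|")
    writeLines(paste0(">", header), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' The packaged holotype reference frame
#'
#' The 658-bp COI barcode of the Heraclides rumiko holotype (GenBank
#' KP173713), which defines the 1..658 position frame every other sequence
#' is anchored to.
#'
#' @return a \code{reference_frame} list with reference_id,
#'   reference_sequence and length.
#' @export
holotype_frame <- function() {
  path <- system.file("extdata", "holotype_KP173713.fasta",
                      package = "barcodegap", mustWork = TRUE)
  rec <- read_barcode_fasta(path)
  reference_frame(rec$specimen_id[1], rec$sequence[1])
}

#' Construct a reference frame
#'
#' @param reference_id id of the reference specimen.
#' @param reference_sequence ungapped IUPAC sequence defining positions 1..L.
#' @return a \code{reference_frame} list.
#' @export
reference_frame <- function(reference_id, reference_sequence) {
  chars <- seq_chars(reference_sequence)
  if (any(chars == "-")) stop("reference sequence must be ungapped")
  bad <- first_invalid_char(chars)
  if (bad > 0L) stop("reference: non-IUPAC character at offset ", bad)
  structure(
    list(reference_id = reference_id,
         reference_sequence = paste(chars, collapse = ""),
         length = length(chars)),
    class = "reference_frame"
  )
}

# Count of identical / compared (both unambiguous ACGT) positions between a
# candidate placement and the reference.
.anchor_score <- function(ref_chars, rec_chars, offset, L) {
  n <- length(rec_chars)
  # record base i sits at frame position offset + i
  pos <- offset + seq_len(n)
  keep <- pos >= 1L & pos <= L
  if (!any(keep)) return(c(matches = 0L, compared = 0L))
  r <- ref_chars[pos[keep]]
  q <- rec_chars[keep]
  mask <- r %in% c("A", "C", "G", "T") & q %in% c("A", "C", "G", "T")
  c(matches = sum(r[mask] == q[mask]), compared = sum(mask))
}

#' Anchor a barcode record onto the reference frame
#'
#' Slides the ungapped record along the reference (no indels: a pure offset
#' mapping), choosing the offset that maximizes the number of identical
#' matches at positions unambiguous in both sequences; ties go to the
#' smallest offset. The reverse complement is tried automatically. Fails
#' unless identity at compared positions reaches
#' \code{1 - max_mismatch_fraction}.
#'
#' @param sequence the record's sequence (string); '-' is read as missing.
#' @param frame a \code{reference_frame}.
#' @param max_mismatch_fraction maximum tolerated mismatch fraction at
#'   compared positions (default 0.15: well above congeneric COI divergence,
#'   low enough to reject non-homologous input).
#' @return list with \code{offset} (0-based: number of frame positions
#'   before the record's first base), \code{row} (length-L string, 'N' at
#'   unsampled positions), \code{orientation} ("forward" or
#'   "reverse_complement"), \code{identity}, \code{matches},
#'   \code{compared}.
#' @export
anchor_to_reference <- function(sequence, frame,
                                max_mismatch_fraction = 0.15) {
  stopifnot(inherits(frame, "reference_frame"))
  L <- frame$length
  ref_chars <- seq_chars(frame$reference_sequence)

  orientations <- list(
    forward = seq_chars(sequence),
    reverse_complement = seq_chars(reverse_complement(sequence))
  )
  best <- NULL
  for (orient in names(orientations)) {
    chars <- orientations[[orient]]
    chars[chars == "-"] <- "N"
    n <- length(chars)
    # match counts for every ungapped offset at once, as a sum of per-base
    # cross-correlations; exact after rounding (integer-valued signal)
    matches_vec <- numeric(L + n - 1L)
    for (base in c("A", "C", "G", "T")) {
      r <- as.numeric(ref_chars == base)
      q <- as.numeric(chars == base)
      matches_vec <- matches_vec +
        stats::convolve(r, q, conj = TRUE, type = "open")[seq_len(L + n - 1L)]
    }
    matches_vec <- round(matches_vec)
    # index k corresponds to offset k - n (offsets -(n-1) .. L-1 ascending)
    k <- which.max(matches_vec)  # first maximum = smallest offset
    cand_matches <- matches_vec[k]
    if (is.null(best) || cand_matches > best$matches) {
      offset <- k - n
      sc <- .anchor_score(ref_chars, chars, offset, L)  # exact recount
      best <- list(offset = offset, orientation = orient,
                   matches = unname(sc["matches"]),
                   compared = unname(sc["compared"]), chars = chars)
    }
  }
  identity <- if (best$compared > 0) best$matches / best$compared else 0
  if (identity < 1 - max_mismatch_fraction) {
    stop(sprintf(paste0(
      "anchoring failed: best identity %.3f (%s orientation, offset %d) ",
      "below required %.3f; input may be non-homologous"),
      identity, best$orientation, best$offset, 1 - max_mismatch_fraction))
  }
  row <- rep("N", L)
  pos <- best$offset + seq_along(best$chars)
  keep <- pos >= 1L & pos <= L
  row[pos[keep]] <- best$chars[keep]
  list(offset = best$offset, row = paste(row, collapse = ""),
       orientation = best$orientation, identity = identity,
       matches = best$matches, compared = best$compared)
}

#' Anchor a set of barcode records into an alignment matrix
#'
#' @param records a \code{barcode_set}.
#' @param frame a \code{reference_frame} (default: the packaged holotype).
#' @param max_mismatch_fraction passed to \code{\link{anchor_to_reference}}.
#' @return a \code{barcode_alignment}: character matrix (specimens x frame
#'   positions, single bases, 'N' = missing) with attributes \code{frame}
#'   and \code{offsets}.
#' @export
align_barcodes <- function(records, frame = holotype_frame(),
                           max_mismatch_fraction = 0.15) {
  validate_barcode_set(records)
  if (nrow(records) == 0L) stop("no records to align")
  if (anyDuplicated(records$specimen_id)) {
    stop("duplicate specimen ids: ",
         paste(unique(records$specimen_id[duplicated(records$specimen_id)]),
               collapse = ", "))
  }
  L <- frame$length
  m <- matrix("N", nrow = nrow(records), ncol = L,
              dimnames = list(records$specimen_id, NULL))
  offsets <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- tryCatch(
      anchor_to_reference(records$sequence[i], frame, max_mismatch_fraction),
      error = function(e) stop("record '", records$specimen_id[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
    m[i, ] <- seq_chars(a$row)
    offsets[i] <- a$offset
  }
  structure(m, frame = frame, offsets = stats::setNames(offsets,
                                                        records$specimen_id),
            class = c("barcode_alignment", class(m)))
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("barcode_alignment:", nrow(x), "specimens x",
      ncol(x), "frame positions\n")
  invisible(x)
}

# Number of unambiguous (ACGT) positions per alignment row.
row_informative <- function(aln) {
  apply(unclass(aln), 1L, function(r) sum(r %in% c("A", "C", "G", "T")))
}
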
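# IUPAC nucleotide alphabet helpers shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Expand an IUPAC code to its base set
#'
#' @param code single IUPAC nucleotide letter.
#' @return character vector of the unambiguous bases the code stands for.
#' @export
iupac_expand <- function(code) {
  set <- IUPAC_SETS[[toupper(code)]]
  if (is.null(set)) stop("not an IUPAC nucleotide code: '", code, "'")
  set
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Handles all ambiguity codes and the gap symbol.
#'
#' @param x character string (5'->3').
#' @return the reverse complement, 5'->3'.
#' @export
reverse_complement <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("non-IUPAC character in sequence: '",
         chars[which(is.na(comp))[1]], "'")
  }
  paste(rev(unname(comp)), collapse = "")
}

# Split an upper-cased sequence string into a character vector of bases.
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# Validate characters; returns the 1-based offset of the first bad character
# or 0L if all are IUPAC letters or '-'.
first_invalid_char <- function(chars) {
  bad <- !(chars %in% c(IUPAC_LETTERS, "-"))
  if (any(bad)) which(bad)[1] else 0L
}
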
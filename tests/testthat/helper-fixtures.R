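# Shared fixtures and caches for the test suite. The expensive
# study-condition cohort (100 specimens per species) is simulated and
# aligned once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

ref_frame <- function() cached("frame", holotype_frame())

# Study-scale cohort: 100 specimens/species, 10 haplotypes/species,
# the 17 published planted sites.
study_cohort <- function() {
  cached("study", {
    sim <- simulate_barcodes(seed = 101)
    aln <- align_barcodes(sim$records)
    list(sim = sim, aln = aln, dm = distance_matrix(aln))
  })
}

# Small cohort for fast pipeline/cluster tests.
small_cohort <- function(n = 15L, seed = 7) {
  cached(paste0("small", n, "_", seed), {
    pair <- default_species_pair(n_specimens = n)
    sim <- simulate_barcodes(pair$model_a, pair$model_b, seed = seed)
    aln <- align_barcodes(sim$records)
    list(sim = sim, aln = aln, dm = distance_matrix(aln))
  })
}

# Build a barcode_alignment by hand from same-length strings (bypasses
# anchoring; used by unit tests that need exact control of the matrix).
make_aln <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  L <- unique(vapply(chars, length, integer(1)))
  stopifnot(length(L) == 1L)
  m <- do.call(rbind, chars)
  rownames(m) <- names(seqs)
  structure(m, class = c("barcode_alignment", class(m)))
}

# A length-658 row: the given base everywhere, substituted at 'at' with
# 'to' (vectorized over positions).
flat_row <- function(base = "A", at = integer(), to = character()) {
  x <- rep(base, 658)
  x[at] <- to
  paste(x, collapse = "")
}

random_iupac_string <- function(n, alphabet = c("A", "C", "G", "T", "N")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
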
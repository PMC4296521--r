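test_that("iupac_match follows base-set intersection semantics", {
  expect_true(iupac_match("K", "T"))
  expect_false(iupac_match("K", "C"))
  expect_true(iupac_match("A", "A"))
  expect_false(iupac_match("Y", "R"))
  expect_false(iupac_match("A", "N"))                      # strict default
  expect_true(iupac_match("A", "N", template_n = "lenient"))
  # symmetry over all non-N code pairs
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  for (x in codes) for (y in codes) {
    expect_equal(iupac_match(x, y), iupac_match(y, x))
  }
})

test_that("ID-tag primers hit the holotype at the expected coordinates", {
  fr <- ref_frame()
  ps <- published_primers()
  f <- find_primer_sites(fr$reference_sequence, ps[["swtl-ID1F"]])
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$start, f$end), c(26L, 53L))
  expect_equal(f$mismatches, 0L)
  expect_equal(f$strand, "+")
  r <- find_primer_sites(fr$reference_sequence, ps[["swtl-ID1R"]])
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(118L, 145L))
  expect_equal(r$strand, "-")
})

test_that("degenerate primer scanning equals the exhaustive oracle", {
  fr <- ref_frame()
  ps <- published_primers()
  for (mm in 0:2) {
    for (nm in c("swtl-mCOIR", "swtl-bCOIF", "swtl-eCOIF")) {
      p <- ps[[nm]]
      pattern <- if (p$orientation == "reverse")
        reverse_complement(p$sequence) else p$sequence
      got <- find_primer_sites(fr$reference_sequence, p, mm)
      want <- oracle_pattern_hits(fr$reference_sequence, pattern, mm)
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
  # absent primer and over-long primer
  none <- primer("none", "forward", "GGGGGGGGGGGGGGGGGGGGGGGG")
  expect_equal(nrow(find_primer_sites(fr$reference_sequence, none)), 0L)
  long <- primer("long", "forward", strrep("A", 700))
  expect_equal(nrow(find_primer_sites("ACGT", long)), 0L)
})

test_that("the ID-tag assay yields a 120-bp product with a 64-bp insert", {
  fr <- ref_frame()
  ps <- published_primers()
  amp <- in_silico_pcr(fr$reference_sequence, ps[["swtl-ID1F"]],
                       ps[["swtl-ID1R"]])
  expect_equal(amp$product_length, 120L)
  expect_equal(amp$insert_length, 64L)
  expect_equal(c(amp$fwd_start, amp$fwd_end), c(26L, 53L))
  expect_equal(c(amp$rev_start, amp$rev_end), c(118L, 145L))
  expect_equal(amp$product_length,
               amp$insert_length + nchar(ps[["swtl-ID1F"]]$sequence) +
                 nchar(ps[["swtl-ID1R"]]$sequence))
})

test_that("amplification fails cleanly for swapped, missing, broken sites", {
  fr <- ref_frame()
  ps <- published_primers()
  expect_error(in_silico_pcr(fr$reference_sequence, ps[["swtl-ID1R"]],
                             ps[["swtl-ID1F"]]), "no amplification")
  trunc <- substr(fr$reference_sequence, 1, 140)  # cuts the reverse site
  expect_error(in_silico_pcr(trunc, ps[["swtl-ID1F"]], ps[["swtl-ID1R"]]),
               "swtl-ID1R")
})

test_that("constructed templates recover their insert exactly", {
  set.seed(71)
  fwd <- primer("toyF", "forward", "ACGTACGTACGTAGGT")
  rev <- primer("toyR", "reverse", "TTGCAATGCCAATGCA")
  for (rep in 1:12) {
    X <- paste(sample(c("A", "C", "G", "T"), sample(20:120, 1), TRUE),
               collapse = "")
    template <- paste0(fwd$sequence, X, reverse_complement(rev$sequence))
    amp <- in_silico_pcr(template, fwd, rev)
    expect_equal(amp$product_length, nchar(template))
    expect_equal(amp$insert_length, nchar(X))
    expect_equal(amp$product_length,
                 amp$insert_length + nchar(fwd$sequence) +
                   nchar(rev$sequence))
    tag <- extract_id_tag(template, fwd, rev)
    expect_equal(tag$sequence, X)
    expect_equal(tag$completeness, "id_tag")
  }
})

test_that("ambiguous shortest pairings error instead of guessing", {
  fwd <- primer("f", "forward", "ACGTACGTAC")
  rev <- primer("r", "reverse", "GGATCCGGAT")
  unit <- paste0(fwd$sequence, strrep("T", 20),
                 reverse_complement(rev$sequence))
  template <- paste0(unit, strrep("C", 30), unit)
  expect_error(in_silico_pcr(template, fwd, rev), "ambiguous")
})

test_that("ID-tag extraction from the holotype spans frame 54..117", {
  fr <- ref_frame()
  ps <- published_primers()
  tag <- extract_id_tag(fr$reference_sequence, ps[["swtl-ID1F"]],
                        ps[["swtl-ID1R"]], "HT-tag")
  expect_equal(nchar(tag$sequence), 64L)
  expect_equal(tag$sequence, substr(fr$reference_sequence, 54, 117))
  expect_equal(attr(tag, "frame_offset"), 53L)
  expect_equal(anchor_to_reference(tag$sequence, fr)$offset, 53L)

  # an N inside the insert survives and the record still anchors
  chars <- seq_chars(fr$reference_sequence)
  chars[80] <- "N"
  tag2 <- extract_id_tag(paste(chars, collapse = ""), ps[["swtl-ID1F"]],
                         ps[["swtl-ID1R"]])
  expect_equal(substr(tag2$sequence, 80 - 53, 80 - 53), "N")
  expect_equal(anchor_to_reference(tag2$sequence, fr)$offset, 53L)
})

test_that("template N policy: strict blocks a primer site, lenient allows", {
  fr <- ref_frame()
  ps <- published_primers()
  chars <- seq_chars(fr$reference_sequence)
  chars[30] <- "N"  # inside the forward ID-tag primer site
  templ <- paste(chars, collapse = "")
  expect_error(in_silico_pcr(templ, ps[["swtl-ID1F"]], ps[["swtl-ID1R"]]),
               "swtl-ID1F")
  amp <- in_silico_pcr(templ, ps[["swtl-ID1F"]], ps[["swtl-ID1R"]],
                       template_n = "lenient")
  expect_equal(amp$product_length, 120L)
})

test_that("overlapping segment schemes report union coverage and overlap", {
  fr <- ref_frame()
  ps <- published_primers()
  pairs <- list(list(fwd = ps[["swtl-bCOIF"]], rev = ps[["swtl-mCOIR"]]),
                list(fwd = ps[["swtl-mCOIF"]], rev = ps[["swtl-eCOIR"]]))
  cov <- scheme_coverage(fr, pairs)
  expect_equal(cov$segments$status, c("ok", "ok"))
  expect_equal(cov$segments$start, c(84L, 261L))
  expect_equal(cov$segments$end, c(324L, 519L))
  expect_equal(cov$covered, 519L - 84L + 1L)
  expect_equal(nrow(cov$junctions), 1L)
  expect_equal(cov$junctions$overlap, 324L - 261L + 1L)
  expect_equal(cov$junctions$gap, 0L)

  # a pair whose primers anneal outside the frame is flagged, not fatal
  mixed <- c(pairs, list(list(fwd = ps[["LepF"]], rev = ps[["LepR"]])))
  cov2 <- scheme_coverage(fr, mixed)
  expect_equal(sum(cov2$segments$status == "ok"), 2L)
  expect_match(cov2$segments$status[3], "no amplification")
  expect_equal(cov2$covered, cov$covered)

  # single pair: coverage equals its amplicon interval
  cov3 <- scheme_coverage(fr, pairs[1])
  expect_equal(cov3$covered, 324L - 84L + 1L)
})

test_that("disjoint segments on a constructed template report the gap", {
  f1 <- primer("f1", "forward", "ACGTACGTACGT")
  r1 <- primer("r1", "reverse", "GGATCCGGATCC")
  f2 <- primer("f2", "forward", "TTGGCCAATTGG")
  r2 <- primer("r2", "reverse", "CATGCATGCATG")
  gap_len <- 25L
  templ <- paste0(f1$sequence, strrep("A", 10),
                  reverse_complement(r1$sequence), strrep("C", gap_len),
                  f2$sequence, strrep("G", 10),
                  reverse_complement(r2$sequence))
  fr <- reference_frame("toy", templ)
  cov <- scheme_coverage(fr, list(list(fwd = f1, rev = r1),
                                  list(fwd = f2, rev = r2)))
  expect_equal(cov$junctions$gap, gap_len)
  expect_equal(cov$junctions$overlap, 0L)
  expect_equal(cov$covered, nchar(templ) - gap_len)
})

test_that("tailed primers match via their gene-specific 3' portion", {
  ps <- published_primers()
  lepf <- ps[["LepF"]]
  expect_equal(lepf$tail5, 18L)
  gene_part <- substring(lepf$sequence, 19)
  templ <- paste0(gene_part, strrep("A", 40), "TTTTTGGGGG")
  hits <- find_primer_sites(templ, lepf)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, nchar(gene_part))
})
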
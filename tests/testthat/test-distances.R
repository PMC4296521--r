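test_that("p_distance masks missing data and counts strict mismatches", {
  d <- p_distance("ACGTN", "ACTTA")
  expect_equal(d$n_compared, 4L)
  expect_equal(d$n_diff, 1L)
  expect_equal(d$fraction, 0.25)

  fr <- ref_frame()
  self <- p_distance(fr$reference_sequence, fr$reference_sequence)
  expect_equal(self$n_diff, 0L)
  expect_equal(self$fraction, 0)

  expect_error(p_distance("NNN", "ANN"), "undefined")
  expect_error(p_distance("ACGT", "ACG"), "length")
})

test_that("percent rounding reproduces the printed percent/bp pairs", {
  a <- flat_row("A")
  expect_equal(p_distance(a, flat_row("A", 1:23, "C"))$percent_1dp, 3.5)
  expect_equal(p_distance(a, flat_row("A", 1:14, "C"))$percent_1dp, 2.1)
  expect_equal(p_distance(a, flat_row("A", 1, "C"))$percent_1dp, 0.2)
  # half-up, not banker's
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

test_that("p_distance is symmetric and monotone under added missingness", {
  set.seed(5)
  for (rep in 1:20) {
    a <- seq_chars(random_iupac_string(80))
    b <- seq_chars(random_iupac_string(80))
    if (!any(a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T"))) next
    dab <- p_distance(a, b)
    dba <- p_distance(b, a)
    expect_equal(dab$n_diff, dba$n_diff)
    expect_equal(dab$n_compared, dba$n_compared)
    a2 <- a
    a2[sample(80, 10)] <- "N"
    d2 <- tryCatch(p_distance(a2, b), error = function(e) NULL)
    if (!is.null(d2)) expect_lte(d2$n_diff, dab$n_diff)
  }
})

test_that("distance_matrix agrees with per-pair calls and with ape", {
  set.seed(14)
  n <- 8L
  seqs <- vapply(seq_len(n), function(i)
    random_iupac_string(120, c("A", "C", "G", "T", "N")), character(1))
  names(seqs) <- sprintf("S%d", seq_len(n))
  aln <- make_aln(seqs)
  dm <- distance_matrix(aln)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- p_distance(unclass(aln)[i, ], unclass(aln)[j, ])
    expect_equal(dm$n_diff[i, j], d$n_diff)
    expect_equal(dm$n_compared[i, j], d$n_compared)
    expect_equal(dm$percent[i, j], d$percent_1dp)
  }
  # independent oracle: ape's raw distance with pairwise deletion
  db <- ape::as.DNAbin(matrix(tolower(unclass(aln)), nrow = n,
                              dimnames = list(names(seqs), NULL)))
  d_ape <- ape::dist.dna(db, model = "raw", pairwise.deletion = TRUE,
                         as.matrix = TRUE)
  expect_equal(unname(dm$fraction), unname(d_ape), tolerance = 1e-12)
})

test_that("distance examples: identical rows and single substitutions", {
  aln <- make_aln(c(a = flat_row("A"), b = flat_row("A"), c = flat_row("A")))
  dm <- distance_matrix(aln)
  expect_true(all(dm$fraction == 0))

  aln2 <- make_aln(c(a = flat_row("A"), b = flat_row("A", 100, "G")))
  expect_equal(distance_matrix(aln2)$percent["a", "b"], 0.2)
})

test_that("haplotype collapsing partitions eligible rows", {
  base <- flat_row("A")
  mut <- flat_row("A", 7, "T")
  aln <- make_aln(c(s1 = base, s2 = base, s3 = base, s4 = mut))
  h <- collapse_haplotypes(aln, min_length = 658L)
  expect_equal(nrow(h), 2L)
  expect_equal(h$count, c(3L, 1L))
  expect_equal(h$representative, c("s1", "s4"))
  expect_equal(sum(h$count), 4L)

  # short rows are ineligible; nothing eligible -> empty table
  short <- make_aln(c(x = paste0(strrep("N", 300), strrep("A", 358)),
                      y = paste0(strrep("N", 300), strrep("A", 358))))
  expect_equal(nrow(collapse_haplotypes(short, 658L)), 0L)
  expect_equal(nrow(collapse_haplotypes(short, 300L)), 1L)
  expect_equal(collapse_haplotypes(short, 300L)$count, 2L)
})

test_that("barcode gap matches exhaustive pair enumeration on toys", {
  seqs <- c(s1 = "AAAA", s2 = "AAAT", s3 = "TTTT")
  aln <- make_aln(seqs)
  labels <- c(s1 = "g1", s2 = "g1", s3 = "g2")
  rep <- barcode_gap(aln, labels)
  oracle <- oracle_gap_extremes(seqs, labels)
  expect_equal(rep$overall_max_within, oracle$max_within)
  expect_equal(rep$min_between, oracle$min_between)
  expect_equal(rep$verdict, "gap_present")
  expect_equal(rep$gap, oracle$min_between - oracle$max_within)

  # identical rows in 2 groups: no gap
  aln2 <- make_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  rep2 <- barcode_gap(aln2, c(a = "x", b = "x", c = "y"))
  expect_equal(rep2$min_between, 0)
  expect_equal(rep2$verdict, "no_gap")

  # singleton groups only: flagged, verdict from between alone
  rep3 <- barcode_gap(make_aln(c(a = "AAAA", b = "TTTT")),
                      c(a = "x", b = "y"))
  expect_true(rep3$flagged)
  expect_equal(rep3$verdict, "gap_present")
})

test_that("neighbor joining recovers a known 4-taxon additive tree", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> path-length matrix
  ids <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  dm <- structure(list(ids = ids, fraction = D, percent = D * 100),
                  class = "barcode_dist")
  tr <- nj_dendrogram(dm)
  expect_equal(unname(ape::cophenetic.phylo(tr)[ids, ids]), unname(D),
               tolerance = 1e-9)
  expect_error(nj_dendrogram(structure(list(ids = c("A", "B"),
                                            fraction = D[1:2, 1:2]),
                                       class = "barcode_dist")),
               "at least 3")
})

test_that("neighbor joining reconstructs random additive trees exactly", {
  set.seed(40)
  for (rep in 1:8) {
    ntax <- sample(5:8, 1)
    tr0 <- ape::rtree(ntax)
    tr0$edge.length <- stats::runif(length(tr0$edge.length), 0.05, 2)
    D <- ape::cophenetic.phylo(tr0)
    dm <- structure(list(ids = rownames(D), fraction = D,
                         percent = D * 100), class = "barcode_dist")
    rec <- nj_dendrogram(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr0), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(unname(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)]),
                 unname(D), tolerance = 1e-6)
  }
})

test_that("negative NJ branch lengths are clamped to zero", {
  # a taxon violating the triangle inequality forces a negative NJ branch
  ids <- c("A", "B", "C")
  M <- matrix(c(0, 0.1, 0.1, 0.1, 0, 0.3, 0.1, 0.3, 0), 3,
              dimnames = list(ids, ids))
  dm <- structure(list(ids = ids, fraction = M, percent = M * 100),
                  class = "barcode_dist")
  raw <- ape::nj(stats::as.dist(M))
  tr <- nj_dendrogram(dm)
  expect_true(min(raw$edge.length) < 0)  # the fixture really exercises it
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("phylip output round-trips dimensions and values", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip(co$dm, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), length(co$dm$ids))
  row2 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(row2[1], co$dm$ids[2])
  expect_lt(max(abs(as.numeric(row2[-1]) - unname(co$dm$fraction[2, ]))),
            1e-6)  # %.6f output rounds at the sixth decimal
})
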
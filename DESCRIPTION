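Package: barcodegap
Title: COI Barcode-Gap Analysis, Diagnostic Characters and Morphometric
    Scores for Cryptic Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrative delimitation of cryptic species pairs from COI
    DNA barcodes and morphometrics: uncorrected p-distances with pairwise
    deletion, haplotype collapsing, barcode-gap (hiatus) analysis,
    neighbor-joining dendrograms, discovery and voting-based application
    of fixed diagnostic nucleotide characters, in-silico PCR with
    IUPAC-degenerate primers including a 64-bp mini-barcode ("ID tag")
    assay for degraded specimens, weighted genitalic and facies
    segregation scores, and a seeded synthetic-data generator that
    reproduces the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
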
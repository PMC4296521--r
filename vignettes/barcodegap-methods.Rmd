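---
title: "Methods: barcode-gap delimitation, diagnostic characters and morphometric scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-gap delimitation, diagnostic characters and morphometric scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

This vignette documents the models, conventions and design choices
behind `barcodegap`, in the spirit of a methods section: what each stage
computes, which knobs matter, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## The position frame and anchoring

Everything is expressed on a 1-based, 658-position reference frame
defined by the packaged reference barcode (the holotype COI sequence,
GenBank KP173713). Butterfly COI barcodes align without insertions or
deletions, so "alignment" reduces to finding, for each record, the
ungapped offset against the reference. `anchor_to_reference()` scans all
offsets (both orientations; reverse-complement input is detected
automatically) and keeps the offset maximizing the count of identical
matches at positions unambiguous in both sequences, ties to the smallest
offset. The scan is computed for all offsets at once as a sum of
per-base cross-correlations (FFT), then the winning offset is recounted
exactly.

Choices worth noting:

* **Identity threshold.** Anchoring fails below 85% identity at
  compared positions (`max_mismatch_fraction = 0.15`). Between-species
  COI divergence in this group is ~3–5%, so homologous input passes
  with a wide margin, while unrelated sequences (expected identity
  ~25%) are rejected. The *objective* is the match count, not identity,
  so a short spurious 100%-identity overlap cannot outcompete the true
  placement.
* **Gaps become missing data.** `'-'` on input is converted to `'N'`:
  with no indels in the system, a gap can only mean an unread base.
* **Overhang is trimmed.** Published full-length barcodes run 658–664
  bp; bases mapping outside positions 1–658 are discarded after
  anchoring because every published coordinate (diagnostic sites,
  primer sites) is defined on the 658-bp frame only. How the original
  analysis trimmed its 659–664-bp reads is not stated; trimming to the
  reference frame is this package's convention.

## Distances, haplotypes and the barcode gap

`p_distance()` implements the uncorrected (Hamming) p-distance with
*pairwise deletion*: a position enters a pair's comparison only when
both rows carry an unambiguous A/C/G/T there. Ambiguity codes count as
missing — the conservative reading of "missing or ambiguous" bases —
which also lets 443-bp partials and 64-bp ID tags participate in the
same matrix as full barcodes. Percentages are rounded half-up to one
decimal (`round_half_up()`), the convention that makes the printed
percent/bp pairs come out exactly: 23/658 → 3.5%, 14/658 → 2.1%,
1/658 → 0.2%. No substitution-model correction (K2P etc.) is applied
anywhere; the analysis is explicitly about raw divergence, and p-distances
are insensitive to transition/transversion structure.

`collapse_haplotypes()` defaults to full-length rows only
(`min_length = 658`) because the haplotype census it mirrors was taken
over full-length barcodes. With rows of unequal completeness the
"identical at all mutually compared positions" relation is not
transitive; the implementation assigns rows greedily, in input order, to
the first class whose *every* member is compatible. For the default
(no missing data) this reduces to exact sequence equality.

`barcode_gap()` reports per-group maximum within-group distance, the
minimum between-group distance, and their difference (the hiatus), all
on the rounded percent scale the census is reported on. Singleton groups
contribute no within-group value; if *no* group has two members the
report is flagged and the verdict rests on the between-group minimum
alone.

`nj_dendrogram()` delegates the agglomeration to `ape::nj()` /
`ape::bionj()` — these are published algorithms, deliberately not
reimplemented — and post-processes negative branch lengths: each
negative edge is zeroed with its residual moved to the sister edge(s),
in a single pass (a repeated pass can oscillate between two negative
siblings). Total tree length is preserved. Dendrograms here are
illustrative; model-based inference is out of scope.

`cluster_groups()` discovers groups by single-linkage at a percent
threshold (default 1.5%, the usual ceiling of subspecies-level
divergence in this tribe, so anything further apart behaves as a
species-level lineage). Single linkage matches the intuition "join
specimens within x% of some member".

## Diagnostic characters

`find_diagnostic_sites()` is a strict per-column fixation scan: a site
qualifies only if *all* non-missing observations in group A equal one
base, all in group B equal a different base, and both groups have at
least `min_coverage` observations there (default 2, so one read cannot
assert fixation; the original sample — 183 + 112 specimens — supported
fixation far more strongly). Ambiguity codes are missing in strict mode;
a lenient mode accepts an ambiguity whose expansion contains the fixed
base and counts it toward coverage. No sub-fixation frequency threshold
is offered: the source analysis itself warns that some positions may
vary in larger samples, but defines no tolerance, so the package exposes
coverage, not a frequency knob.

Classification of unknowns is deliberately minimal — majority voting
over scorable sites with the margin reported — because the source
defines the character list but no classifier; voting is the faithful
minimal choice and degrades gracefully for ID tags that cover only 3 of
the 17 sites. `select_diagnostic_region()` finds the window with the
most fixed differences (ties to the smallest start), the criterion used
to place a mini-barcode assay for degraded specimens.

## In-silico PCR

Primers are stored 5'→3' as printed; reverse primers are
reverse-complemented internally and all coordinates reported on the
template's forward strand. A hit requires the full primer inside the
template (no partial 3' annealing — templates here are barcode
sequences, not genomic context). A template `'N'` matches nothing in
strict mode (missing data cannot support a primer site); a lenient mode
is available. `max_mismatches` defaults to 0 and is configurable up to a
few mismatches, modeling the fallback primers used when exact
amplification fails. Among valid forward-before-reverse pairings the
unique shortest product wins; a tie is an error listing the
alternatives, never a guess. The universal tailed primers (M13 tails)
carry a `tail5` annotation and are matched by their 3' gene-specific
portion only.

One empirical caveat the tests document: the outer whole-barcode primers
anneal *outside* the 658-bp frame (their binding sites lie upstream of
position 1 or downstream of position 658 on genomic DNA), so on a
barcode-only template they are correctly reported as non-amplifying;
coverage-scheme demonstrations use the internal overlapping pairs, which
bracket positions 84–519 with a 64-bp overlap.

## Morphometric scores

The two composite axes are applied literally to raw measurements, with
the published weights as fixed constants:

* genitalic: `0.6·(U-B angle, radians) + 0.2·(B−A)/(C−B) + 0.2·G/H`
* facies: `0.15·YL + 0.4·F/P + 0.4·T/V + 0.05·W/D`, `YL ∈ {0, 1}`

Whether the original plot standardized measures before weighting is not
stated; the formulas are taken at face value on raw values. The scores
are scale-free in the length measures (only ratios enter), and the
genitalic score shifts by exactly 0.6·δ under an angle shift δ — both
properties are tested. Degenerate denominators (C = B, zero P/V/D)
raise errors rather than returning infinities: they indicate measurement
mistakes, not biology. Angles may arrive in degrees via an option and
are converted to radians.

`hiatus_test()` declares separation when the two groups' score ranges
are disjoint and classifies by the midpoint of the inner range edges — a
deterministic, scale-free threshold. When the ranges overlap the same
midpoint is still used for the misassignment list (the overlapping case
is undefined in the source; the midpoint is this package's convention).
`single_measure_accuracy()` scans all candidate thresholds (midpoints
between adjacent distinct values, both polarities) exhaustively.

## What the synthetic generator emulates — and what it does not

`simulate_barcodes()` reproduces the *statistical shape* of the study
conditions, with defaults fixed to those conditions:

* two species whose modal barcodes differ at exactly the 17 packaged
  diagnostic positions (≈2.6% of 658);
* 10 haplotypes per species: a dominant modal haplotype plus eight
  single-substitution and one double-substitution variant, so pairwise
  within-species distances are 1–3 bp (≤ 0.5% of the frame,
  analytically guaranteed, matching the observed cap);
* haplotype frequencies with a modal weight of 67 against 27 spread
  geometrically — at `n_specimens = 94` (the full-length type-series
  census) the modal haplotype count is exactly 67; counts are
  apportioned by largest remainder with a floor of one specimen so the
  realized haplotype count always equals the model (multinomial
  sampling could silently drop rare haplotypes);
* 100 specimens per species by default;
* within-species substitutions are placed only outside the planted
  positions and outside the ID-tag assay region (frame 26–145: both
  primer sites plus the 64-bp insert), so planted diagnostics remain
  strictly fixed and exact-match ID-tag amplification always succeeds
  on simulated specimens;
* substitutions are uniform over the three alternative bases — no
  transition/transversion bias, which p-distances cannot see anyway.

`simulate_id_tags()` degrades a seeded fraction of records to their
64-bp insert and another fraction to 5'-443-bp partials (which end the
real partial reads retained is not stated; 5' is this package's
convention).

`simulate_morphometrics()` draws each group's angle and ratios from
disjoint uniform intervals (defaults: angle 1.4–1.6 rad vs 0.2–0.4 rad,
ratios 0.9–1.3 vs 0.3–0.7, YL 1 vs 0) and reconstructs raw distances
from the drawn ratios. With these defaults the composite-score supports
are disjoint by construction: the genitalic score lies in
[1.20, 1.48] for one group and [0.30, 0.52] for the other. Hybrids are
convex mixes of one parental draw from each group with mixing weight
λ ∈ [0.45, 0.55]; because a ratio of mixed numerators and denominators
is a mediant (it lies between the parental ratios) and the angle mixes
linearly, hybrid genitalic scores fall in [0.564, 1.156] — *strictly
between* the two parental ranges. On the facies axis no such guarantee
holds (YL must snap to 0 or 1), which mirrors the real observation that
intermediates are conspicuous on some axes and not others.

What the generator does **not** emulate: coalescent or mutation-process
realism, rate variation along the gene, geographic structure,
saturation, heteroplasmy, or sequencing error. Passing the recovery
tests therefore shows the *pipeline* is correct under the assumed
structure — clean fixation, a true gap, disjoint morphometric supports —
not that real data will be as clean; on real data the same code simply
reports whatever weaker structure is present.

## Problem sizes and numerical choices in the test suite

The test suite exercises the study-scale cohort once (100 specimens per
species, 658-bp frame — a 200×658 alignment and its 200×200 distance
matrix) and uses smaller cohorts (5–20 specimens per species) for the
other end-to-end checks; property-style tests run 6–20 replicates over
random 4–8-taxon trees, random 40–50-column matrices, and random
20–120-bp inserts under fixed seeds. Distance matrices are computed as
per-base indicator matrix products; anchoring uses FFT
cross-correlation with an exact recount at the winning offset —
both exact, not approximate, algorithms. Floating-point comparisons in
tests use explicit tolerances only where text round-trips (`%.6f`
PHYLIP output) or trigonometric conversions are involved.

## Known limitations

* Two groups only: multi-group diagnostics and gaps are out of scope.
* No gapped alignment: records with real indels relative to the
  reference will anchor poorly and fail the identity threshold.
* The haplotype-compatibility partition is order-dependent when rows
  have heavy missingness (greedy assignment); for full-length rows it
  is exact.
* The concordance flag in the pipeline treats absent evidence as
  silent, so a specimen with only one evidence line is trivially
  concordant.
* Specimens intermediate between groups are flagged, never
  auto-excluded: the source excluded its contact-zone specimens from
  the formal series by judgment, not by a stated quantitative rule, and
  the package does not invent one.
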
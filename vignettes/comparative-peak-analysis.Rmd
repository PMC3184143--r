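---
title: "Comparing ChIP-Seq peak callers and their expression associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ChIP-Seq peak callers and their expression associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcompare)
```

## The problem

ChIP-Seq peak callers disagree, sometimes dramatically: on the same mapped
reads, different programs report peak sets differing severalfold in count,
total base-pair coverage, and position relative to genes. For a repressive
histone mark such as H3K27me3, the downstream biological question — is the
mark near a gene associated with low expression? — must therefore be asked
*per caller*, and a careful analysis checks whether the biological
conclusion survives the choice of caller. `peakcompare` implements that
comparative workflow: per-caller peak statistics, base-pair consensus
support between callers, peak heights from the read pileup, peak-to-gene
classification, expression discretization, association testing, term
enrichment, and evaluation against a gold standard.

All coordinates are 0-based half-open (BED convention); GFF3 input is
converted at the boundary. Chromosome names are taken verbatim — a
mismatch is an error, never silently renamed — because silent renaming
hides data errors.

## Per-caller peak statistics

`summarize_peaks()` reports peak count, union base-pair coverage, percent
genome coverage and bandwidth (peak length) mean/SD. Two deliberate
conventions:

* **Coverage uses the interval union**, so overlapping peaks within one
  caller's set never double-count a base pair. **Bandwidth statistics use
  the raw peaks.** The two can disagree slightly (`bandwidth_mean` vs
  `coverage_bp / peak_count`); both are exposed (`coverage_per_peak()`)
  because published tables have been computed both ways.
* **`genome_size` is an explicit parameter.** Percent coverage in
  published tables is often computed against a published assembly constant
  (e.g. 389 Mb for rice) rather than the summed lengths of the sequences
  actually used; passing the constant reproduces such tables exactly.
* Bandwidth SD uses the sample (n − 1) convention.

## Base-pair consensus support

Every base pair is labelled with the number of programs whose peaks cover
it (`build_support_track()`), and each program's peak base pairs are then
binned by that support count (`support_profile()`): if a program covers
200 bp and 60 of them are covered by exactly one other program, 30% of its
base pairs have support 2. Each program contributes at most one supporter
per base pair regardless of within-set overlap — support counts programs,
not peaks. The implementation is run-length-encoded coverage (a sweep over
sorted breakpoints, O(n log n)); the test suite checks it against a
per-base counting oracle on randomized small genomes, where the two must
agree exactly.

## Peak height

Height is max depth − min depth of the ChIP pileup inside the peak
(`peak_height()`), averaged per program (`mean_peak_height()`). Heights
use raw ChIP depth, not ChIP − Input; `normalize_tracks()` (scaling Input
to the ChIP total) exists for display and diagnostics. Positions not
covered by any bedGraph step have implicit depth 0 and by default
participate in the minimum; `include_gaps = FALSE` restricts the minimum
to covered positions, since it is genuinely ambiguous which convention a
given published analysis used.

## Peak-to-gene classification

Each gene gets exactly one label with precedence
**within > upstream > downstream > none** (`classify_genes()`): within if
any peak overlaps the gene body by ≥ 1 bp, else upstream if any peak
overlaps the upstream window, else downstream, else none. Defaults:
2 kb windows on both sides, strand-aware (for a − gene, upstream is to
the right). Strand-awareness matches the biological reading of
"promoter-proximal", but since analyses have been published both ways a
strand-ignorant mode is provided for sensitivity analysis. The ≥ 1 bp
overlap threshold is the least arbitrary default; genes matching more than
one category before precedence are counted and reported as a diagnostic.

## Expression discretization

Raw expression values are log10-transformed and z-scored with the sample
SD (`compute_zscores()`), then cut into high (z ≥ 0.5), middle and low
(z ≤ −0.5) by `discretize_expression()`. The ±0.5 SD cuts are a
conventional three-way split and are fully configurable — published splits
(e.g. 33/28/39%) depend on the specific data and exact cutoffs, so the
cuts are a knob, not a constant. `category_percents()` reports shares with
the largest-remainder method so they sum to exactly 100, the convention
behind published splits whose rounded parts sum to 100.

## Association testing

`build_contingency()` cross-classifies genes (3 expression categories × 4
labels); `conditional_probabilities()` gives P(expression | label) per
column; `hypergeometric_cell_test()` tests each cell for
over-representation with the upper-tail hypergeometric
P(X ≥ k), X ~ Hypergeom(N, K = row marginal, n = column marginal). The
test is one-sided by default — in published grids the complementary cells
show p ≈ 1.0, the signature of a one-sided test — and the
parameterization is symmetric in which marginal plays "draws". No
multiple-testing correction is applied by default (matching the common
raw-p cutoff of 10⁻² for such 12-cell grids); `adjust = "BY"` is available
for more rigor. `binomial_genic_test()` is the companion upper-tail
binomial test of genic-read enrichment, with the Input library's genic
fraction as the natural null `p0`.

## Term enrichment

`enrich()` performs hypergeometric term enrichment of a query list against
the background of all annotated genes with Benjamini–Yekutieli adjustment
(p(i) · m · H(m) / i, step-up monotonized, capped at 1) — valid under the
arbitrary dependence that overlapping gene sets create. Terms annotating
fewer than 2 background genes are dropped by default (singleton terms give
degenerate tests). If a child → parent term map is supplied, annotations
are propagated to ancestors first, as ontology-aware tools do; without
one, terms are taken as given so the core stays testable without ontology
files.

## Gold-standard evaluation

`collapse_label()` reduces positional labels to enriched (+) /
unenriched (−), and `evaluate_predictions()` tallies per-program confusion
counts against a gold standard. The package ships a transcribed wet-lab
ChIP-PCR table (23 rice genes, 18 enriched and 5 unenriched, with four
real programs' calls) as `chip_pcr_table()`; on it, the four programs
recover 13, 2, 18 and 12 of the 18 enriched genes, with a single false
positive for the most permissive caller.

## The synthetic-study generator

`simulate_study()` builds a complete miniature study so every stage is
testable without external downloads. What it emulates:

* a multi-chromosome genome (default 3 × 6 Mb = 18 Mb) with 2,000
  non-overlapping genes spaced at least 2 × 2 kb apart, so that every
  planted domain lies in exactly one gene's body-or-flank and planted
  labels are unambiguous;
* true repressive domains on 25% of genes, placed within the body (50%),
  in the strand-relative upstream window (30%) or downstream window (20%);
* log10-normal expression (mean 2, SD 1 on the log scale) with a planted
  repression association: marked genes fall into the bottom expression
  tercile with odds multiplied by 8 (with `repression_odds = 1` the
  marginal distribution is exactly log-normal and the null holds exactly);
* Poisson pileups drawn per 10 bp bin — background 2 reads/bp, 8-fold
  enrichment over domains — one draw per bin rather than per bp to keep
  tracks compact, since every downstream operation is agnostic to step
  widths;
* K virtual callers that distort the truth with per-caller sensitivity,
  Gaussian boundary jitter, uniform false peaks placed outside true
  domains (so ground-truth labels stay unambiguous), and gap-based peak
  merging. The four default profiles span the qualitative behaviours of
  real callers: conservative/sharp, permissive/broad with many false
  positives, sensitive without control, and aggressively merging.

The seed fully determines the output, including the written files
byte-for-byte; pileup generation happens last on the random stream so
`tracks = FALSE` (used in simulation-heavy tests) changes nothing else.

What it does **not** emulate: read-level artifacts (mappability, duplicate
reads, fragment-size effects, GC bias), gene-density or gene-length
biases, correlated caller errors, and the genuinely different windowing
algorithms of real callers. Passing tests on this generator therefore
demonstrate the correctness of the *analysis* computations and the
recoverability of a planted association — not that any real caller is
well-approximated by a jittered Bernoulli thinning of the truth.

Default sizes were chosen so the planted (low | upstream) association is
comfortably detectable (about 150 upstream-marked genes among 2,000) while
a full simulation with tracks takes about a second; the test suite runs
smaller genomes (1–4 Mb, 150–400 genes) where a property holds at any
scale.

## Numerical and degenerate-input choices

* Exact tails come from `phyper`/`pbinom`; tests verify them against
  explicit combinatorial enumeration for N ≤ 30 at 1e−10 relative
  tolerance.
* Empty peak collections: summaries report count 0 with absent (NA)
  bandwidths; support profiles and mean heights refuse them (the
  denominator would be 0).
* Zero-marginal columns in conditional probabilities are reported absent
  (NA), not as errors.
* bedGraph steps are canonicalized on read: sorted, overlap rejected,
  adjacent equal-depth steps merged; zero-depth steps are preserved so
  write/read round trips are exact.
* Expression values ≤ 0 are rejected at parse time because the log10
  transform is undefined there; zero variance across genes is an error.
* Peak merging uses strictly-closer-than-gap semantics, so `merge_gap = 0`
  merges only overlapping peaks and leaves touching peaks separate.

## Known limitations

* Base-pair support and coverage are computed with dense per-chromosome
  run-length encodings; genomes far beyond the hundreds-of-Mb scale would
  want an interval-sweep without materialized coverage vectors.
* The gold-standard fixture is a transcription of a small wet-lab table;
  its 23 genes support exact count checks, not statistical claims.
* The association test treats genes as exchangeable; no correction for
  gene length or density is attempted (longer genes are more likely to
  receive a "within" label by chance).
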
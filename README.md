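# peakcompare

Comparative analysis of ChIP-Seq peak calls and their association with
gene expression.

Different peak-calling programs, run on the same mapped reads, can report
peak sets that differ severalfold in number, total coverage and position
relative to genes. For a repressive histone mark such as H3K27me3 the
biological question — *is the mark near a gene associated with low
expression?* — should therefore be asked per caller, and the conclusion
trusted only if it survives the choice of caller. `peakcompare` implements
that workflow for anyone benchmarking peak callers or analysing a
repressive-mark ChIP-Seq experiment:

* **Peak statistics** per caller: count, union base-pair coverage, percent
  genome coverage, bandwidth mean/SD (`summarize_peaks`, `metrics_table`).
* **Consensus support**: the fraction of each caller's peak base pairs
  covered by exactly 1..K callers, counting programs (not peaks) per base
  pair (`build_support_track`, `support_profile`).
* **Peak height** from the read pileup: max − min ChIP depth per peak,
  averaged per caller (`peak_height`, `mean_peak_height`), plus
  ChIP/Input total normalization (`normalize_tracks`).
* **Peak-to-gene classification** with strand-aware flanking windows and
  precedence within > upstream > downstream > none (`classify_genes`).
* **Expression discretization**: log10 → z-score → high/middle/low
  (`compute_zscores`, `discretize_expression`).
* **Association tests**: 3 × 4 contingency table, conditional
  probabilities P(expression | label), and a one-sided hypergeometric test
  per cell, P(X ≥ k) with X ~ Hypergeom(N, K, n); plus a binomial test of
  genic-read enrichment (`build_contingency`, `hypergeometric_cell_test`,
  `binomial_genic_test`).
* **Term enrichment** with Benjamini–Yekutieli FDR adjustment (`enrich`).
* **Gold-standard evaluation** of collapsed enriched/unenriched calls,
  including a packaged wet-lab ChIP-PCR table of 23 rice genes
  (`evaluate_predictions`, `chip_pcr_table`).
* **A synthetic-study generator** — genome, genes, log-normal expression
  with a planted repression association, Poisson pileups, and K distorted
  "virtual caller" peak sets — so the whole pipeline is testable end to
  end (`simulate_study`).

File formats: BED (peaks), GFF3 (genes), bedGraph (pileups), TSV
(expression, annotations, gold standards). Internally everything is
0-based half-open.

## Worked example

The `analysis/` directory is a numbered workflow over one seeded synthetic
study (18 Mb genome, 2,000 genes, 500 true repressive domains, four
virtual callers). Run the stages in order from the repository root:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_peak_metrics.R
...
Rscript analysis/08_validation.R
```

Stage 2 prints the per-caller comparison table (also written to
`results/peak_metrics.tsv`):

```
    program peak_count coverage_bp percent_coverage bandwidth_mean bandwidth_sd
1     sharp        278      318079              1.8         1144.2        417.7
2     broad        571      643571              3.6         1127.1        700.2
3 nocontrol        440      508865              2.8         1156.5        450.7
4    merged        420      489371              2.7         1165.2        448.5
5     truth        500      588820              3.3         1177.6        415.0
```

The conservative `sharp` caller finds barely half the true domains while
the permissive `broad` caller overshoots the genome fraction covered.
Stage 3 shows the same story as consensus support — 26.52% of `broad`'s
peak base pairs are supported by no other caller, against 2.66% for
`sharp`. Stage 6 is the biological punchline: despite those differences,
every caller yields the same association between an upstream peak and low
expression,

```
sharp      P(low|upstream)=0.55 P(low|none)=0.29  p(low,upstream)=2.82e-05
broad      P(low|upstream)=0.53 P(low|none)=0.25  p(low,upstream)=1.48e-07
nocontrol  P(low|upstream)=0.56 P(low|none)=0.27  p(low,upstream)=3.38e-08
merged     P(low|upstream)=0.56 P(low|none)=0.27  p(low,upstream)=6.11e-08
```

i.e. a gene with an upstream peak is about twice as likely to sit in the
low-expression tercile as a gene with no peak, and every caller flags the
(low, upstream) cell at p < 0.01 — the planted repression association is
recovered regardless of caller. Stage 8 evaluates the packaged ChIP-PCR
gold standard: of the 18 wet-lab-enriched genes the four real programs
recover 13, 2, 18 and 12, and the most permissive program is the only one
with a false positive among the 5 unenriched genes.

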
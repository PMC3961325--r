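# wnttargets

Integrative calling of direct Wnt/CTNNB1 target genes from ChIP-seq
chromatin occupancy and siRNA-knockdown expression profiling.

Aberrant stabilisation of CTNNB1 (β-catenin) drives most colorectal
cancers: nuclear CTNNB1 binds chromatin through TCF/LEF factors and
activates Wnt target genes. Binding alone does not imply regulation, and
expression change alone cannot separate direct from secondary effects —
calling *direct, functional* targets requires both data types on the same
cells. `wnttargets` implements that integration as a set of pipeable,
tibble-first R functions, for analysts working with peak intervals (BED),
gene models (refFlat), genome FASTA, two-channel knockdown expression
tables and clinical follow-up data.

## What it computes

* **Peak annotation** — each peak is assigned by its center point to one of
  promoter (2 kb upstream of the TSS), 5′-UTR, exon, intron, 3′-UTR,
  downstream (2 kb past the TTS) or intergenic, with the precedence
  promoter > 5′-UTR > exon > intron > 3′-UTR > downstream. Enrichment of a
  category is tested against a null built by re-placing length-matched
  peaks uniformly at random (`shuffle_peaks()`), with the add-one empirical
  p-value `p = (1 + #{null ≥ obs}) / (B + 1)`.
* **Peak-to-gene linking** — a gene is *bound* when a peak center lies
  within 20 kb of its TSS (inclusive).
* **Motif enrichment** — degenerate IUPAC motifs (e.g. AP-1 `TGAYTCA`)
  scanned on both strands; peak-level hit rate tested against
  length-matched random genomic fragments via a binomial upper tail.
* **Running-sum (GSEA/KS) enrichment** — for a gene set *S* in a ranked
  list of *N* genes, the running sum gains `|m_i|^w / Σ_S |m_j|^w` at each
  hit (`1/|S|` for the classic `w = 0` statistic) and loses `1/(N − |S|)`
  at each miss; ES is the extremum, with gene-label permutation p-values
  and `NES = ES / mean(|ES_null| of the same sign)`.
* **Combinatorial target calling** — the direct-target signature is the set
  of genes that are bound *and* down-regulated in **both** knockdown
  channels with `p < 0.01` and log10 ratio `< −0.2` (strict). Log10 ratios
  convert to signed fold changes as `r ↦ sign(r)·10^|r|`.
* **Set overlap** — representation factor `RF = k·N/(|A|·|B|)` and exact
  hypergeometric upper-tail `P(X ≥ k)` under a fixed universe (default
  N = 20000).
* **Survival stratification** — per-sample mean signature expression on
  mean-centred arrays, median split into high/low expressers, Kaplan–Meier
  curves and the Mantel–Haenszel log-rank test.
* **Synthetic data** — a seeded generator (`simulate_wnt_study()`) that
  emulates every input with planted ground truth, so the full pipeline runs
  and is validated offline.

Result objects come with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(wnttargets)
library(dplyr)

study <- simulate_wnt_study(7)             # genome, peaks, expression, cohort
bound <- link_peaks_to_genes(study$peaks, study$sim$genes)

permutation_enrichment(study$peaks, study$sim$genes, study$sim$genome,
                       "promoter", annotation_config(n_permutations = 999))
#>   category  observed  null_mean    null_sd p_value n_permutations
#> 1 promoter 0.1266667 0.09913914 0.01703121   0.066            999

motif_enrichment_test(study$peaks, study$sim$genome, "TGAYTCA")
#>   n_peaks hits rate background_rate     fold      p_value
#> 1     300   72 0.24      0.08033333 2.987552 3.373841e-17

sig <- call_targets(study$expression, bound) |> summarize_signature()
nrow(sig)                                   # 40 -- all 40 planted targets,
all(sig$symbol %in% study$targets)          # TRUE   no false positives

overlap_report(sig$symbol, study$targets, N = 20000)
#> Gene-set overlap: 40 of 40 x 40 (universe 20000)
#>   expected 0.080, representation factor 500.000, p = 7.716e-125

stratified_survival(study$cohort$matrix, sig$symbol, study$cohort$clinical)
#> Signature survival stratification: 232 samples (low n=116, high n=116)
#> Log-rank test: chi-square = 22.0582 (1 df), p = 2.645e-06
```

The promoter fraction (12.7%) exceeds the shuffle-null mean (9.9%) because
bound-gene peaks are planted near TSSs; the AP-1 motif is ~3-fold enriched
over length-matched random fragments because the generator plants copies
inside bound-gene peaks; the median-split log-rank test detects the
planted hazard ratio of 2 in the 232-sample cohort.

## A note on scale

The defaults of the synthetic generator (two 2-Mb chromosomes, 200 genes,
300 peaks, 40 planted targets) are sized so that every stage — including
permutation nulls and calibration suites — runs in seconds to minutes on a
laptop. See the methods vignette (`vignettes/wnt-target-pipeline.Rmd`) for
the model, its assumptions and the design decisions.
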
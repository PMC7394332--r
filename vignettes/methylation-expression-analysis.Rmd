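---
title: "Linking CpG methylation to gene expression: the methylink pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking CpG methylation to gene expression: the methylink pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylink)
```

## The analysis model

`methylink` asks, for every gene separately, whether the methylation of the
CpG probes annotated to that gene differs systematically between samples in
which the gene is highly expressed and samples in which it is not. The
design is deliberately non-parametric and per-gene:

* **Stratification, not regression.** Samples are ranked by the gene's
  expression and cut into Up/Medium/Down tertiles. Methylation is then
  contrasted *between* tertiles. This makes no linearity assumption about
  the methylation–expression link and is robust to the heavy skew of
  expression data.
* **Beta values in [0, 1].** Methylation input must be beta values (ratio
  of methylated to total signal). Differences of medians of betas — the
  β-difference — are therefore bounded in [−1, 1] and directly
  interpretable as a methylation-fraction shift.
* **Non-parametric significance.** Beta values routinely fail normality,
  so tertile contrasts use the two-sample Kolmogorov–Smirnov test.
  Expression contrasts, by convention of the field, use Welch's t-test and
  a signed fold change.
* **Correlation as confirmation.** A Pearson correlation between
  expression and methylation over *all* samples (not per tertile)
  summarizes direction and strength; it is intentionally the last,
  confirmatory statistic rather than the primary screen.

Both matrices must arrive pre-normalized and with unique, harmonized ids;
the sample universe is the intersection of the two matrices' sample ids.
Gene rows that are entirely null or zero are dropped, and genes with fewer
than three informative samples are skipped with a logged reason.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `is_log` | `FALSE` | Declares expression is log2(x+1); switches the fold-change formula to `2^|mA−mB|`. |
| `batch_size` | 1000 genes | Genes processed per batch; bounds memory on probe-dense genomes. |
| `workers` | 1 | Forked workers over gene batches; output is bit-identical for any count. |
| `ks_pooling` | `"pooled"` | Group-level KS compares pooled member beta values; `"summary"` compares per-sample median profiles instead. |
| `beta_diff_min` | 0.1 | Minimum \|β-difference\| (a 10-point methylation shift is a common biological-relevance floor). |
| `ks_alpha`, `ttest_alpha` | 0.01 | Significance levels for the KS and t-test filters. |
| `fc_min` | 2 | Minimum \|fold change\| between expression groups. |
| `pearson_alpha` | 0.05 | Significance level for the correlation filter. |
| `top_k` | 50 | Records per direction in the top-correlated lists. |
| `pairs` | `"up_down"` | Which tertile pair(s) the pairwise filters threshold; Up vs Down is the largest contrast. |

## Numerical and procedural choices

Several points are underdetermined by the method's verbal description; the
package fixes them as follows and tests each one.

* **Ordering ties.** Descending expression order breaks ties by ascending
  sample id with a radix (C-locale) sort, so results never depend on the
  session locale or input order.
* **Tertile remainder.** With `n = 3q + r`, Up receives an extra sample
  when `r ≥ 1` and Medium when `r = 2`. Any fixed rule satisfies the
  size-balance invariant (|difference| ≤ 1); this one favours the
  high-expression group that downstream contrasts emphasize.
* **Fold-change branches.** For concordant linear means the ratio is taken
  as `max(|mA|,|mB|)/min(|mA|,|mB|)`, so the magnitude is always ≥ 1 for
  both positive and negative concordant pairs. Means that straddle or touch
  zero fall to the difference branch (a ratio across zero is undefined).
  Equal means return magnitude 1 (ratio and log branches) or 0 (difference
  branch) with positive sign. The three pairs are computed as Up vs Medium,
  Up vs Down, Medium vs Down, first-named group as A.
* **Degenerate t-tests.** Two equal-length groups whose elementwise
  difference is all zero carry no contrast and return `NA` (as do groups
  smaller than two, or two essentially constant groups). This mirrors the
  guard in the original formulation rather than reporting p = 1.
* **KS branches.** The exact two-sample distribution is used when both
  groups have ≤ 25 finite values, the asymptotic distribution otherwise.
  At typical cohort sizes tertiles fall in the exact regime; note the exact
  p-value is then discrete, so its attainable significance levels lie just
  below the usual round thresholds (for 20 vs 20, the largest level below
  0.05 is ≈ 0.0335). Interpreting null-calibration rates requires this.
* **Missing values.** Never imputed. Medians/means and KS drop missing
  values within groups; Pearson uses pairwise-complete observations (≥ 3
  required, both vectors non-constant). A record is always emitted, with
  `NA` where a statistic is undefined, and filters treat `NA` as failure.
* **Group-level Pearson.** Pooling replicated beta values across member
  probes would replicate the paired expression values and inflate the
  sample size, so the group correlation pairs each sample's expression
  with its *median beta across member probes*. Group KS, by contrast, does
  use pooled values (the grouped dataset is what the tertile split is
  applied to); `ks_pooling = "summary"` exposes the per-sample-summary
  alternative for sensitivity analysis.
* **Island grouping.** A probe's island relation is a probe property, so
  island groups deduplicate by probe id even when a probe has several
  gene-region records; probes with no island relation are classed
  `OpenSea`, excluded from island groups but retained everywhere else.
* **Keys.** Records are keyed `probe_region_gene`
  (`cg02626719_1stExon_ARMCX2`). Probe ids and region labels never contain
  an underscore, so keys are parsed by splitting from the left at most
  twice; gene symbols containing underscores survive intact.
* **Filter semantics.** The cascade is a pure conjunction (order affects
  only the logged per-step survivor counts). The β-difference and
  fold-change filters threshold magnitudes by default, keeping hyper- and
  hypomethylation (and up/down-modulation) symmetrically; signed
  thresholds are available via `use_magnitude = FALSE`. Where a pair
  selector names several pairs, every selected pair must pass.
* **Determinism.** Genes are processed independently and merged by sorted
  gene id, then tables are sorted by (gene, key); output files are
  byte-identical across worker counts and batch partitions, which the test
  suite asserts with file checksums.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` builds the three inputs plus a truth table. Per
gene, expression is log-normal (baseline `runif(log 100, log 1000)`,
spread `sdlog ∈ [0.4, 0.8]`); each gene carries one probe per region class
by default. In a `fraction_regulated` subset (default 0.3) the
promoter-class probes (TSS1500/TSS200/5'UTR) follow
`beta = logistic(a − slope·z)` where `z` is the standardized log2
expression; a `fraction_body_positive` subset (default 0.2) uses `+slope`
on Body probes; all other probes are expression-independent. Gaussian
noise (`noise_sd`, default 0.05) is added on the beta scale and clipped to
[0, 1] — the logistic link keeps values in range so clipping only trims
noise excursions. Island relations are drawn per region class with fixed
proportions (promoter probes mostly Island/Shore, body probes mostly open
sea). The truth table of planted directions is a first-class output, so
recovery checks never reach into generator internals.

The generator does **not** mimic real 450k probe-density geography,
spatial correlation along chromosomes, cell-type composition effects,
batch structure, bimodal beta distributions of mixed tissues, or
many-to-many probe sharing between overlapping genes (those cases are
covered by constructed annotation fixtures in the tests). Passing the
recovery and calibration checks therefore demonstrates the pipeline's
correctness on its own model of the data, not performance on any
particular cohort.

The reference conditions used throughout the test suite are 50 genes × 60
samples × 6 probes/gene (slope 3, noise 0.05) for signal recovery, and
500 genes of null probes for calibration — sizes chosen so the whole suite
exercises every stage, including byte-level determinism across workers and
batches, at desk scale.

## Known limitations

* Statistics are reported raw; no multiple-testing correction is applied
  before the filter cascade (thresholds are on nominal p-values, as in the
  original filtering practice). Users screening genome-wide should treat
  survivor lists as candidate sets, not inference.
* Exact string matching links annotation gene symbols to expression ids;
  unmatched symbols are logged, not resolved.
* A gene's Pearson correlation at group level depends on the per-sample
  median summary; alternatives (mean, trimmed mean) are not exposed.
* The region × island cross-classification appears only in the direction
  summaries, not as a fifth grouped statistics table.
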
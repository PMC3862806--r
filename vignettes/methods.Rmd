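---
title: "Methods: moderated d-statistics, permutation FDR, and the synthetic cohorts behind the tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated d-statistics, permutation FDR, and the synthetic cohorts behind the tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samde)
```

## The model

samde analyzes probeset-by-sample matrices of log2 intensities from small
two-group designs. The per-gene score is the moderated d-statistic

$$d_i = \frac{r_i}{s_i + s_0},\qquad
s_i = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
\frac{\sum_1 (x-\bar x_1)^2 + \sum_2 (x-\bar x_2)^2}{n_1+n_2-2}},$$

where $r_i$ is the difference of group means (first contrast group minus
second, so positive $d$ means increased in the first group). The additive
offset $s_0$ borrows variance information across genes: it damps the scores
of genes whose observed scatter is small by chance, which would otherwise
dominate the tails of $d$. With $s_0 = 0$ the statistic reduces exactly to
the pooled two-sample t.

Inference is permutational. Group labels are permuted — all
$\binom{n_1+n_2}{n_1}$ distinct assignments are enumerated whenever that
number fits within the permutation budget `B`, otherwise `B` distinct
assignments are sampled — and $d$ is recomputed for each. Sorting each
permuted vector and averaging the $i$-th smallest values gives the expected
order statistics $\bar d_{(i)}$. For an offset $\Delta$, genes with
$d_{(i)} - \bar d_{(i)} > \Delta$ define the up cutoff (the smallest such
$d$), and symmetrically for the down cutoff, so a single symmetric offset
induces asymmetric call regions, which matters in cohorts where changes are
predominantly one-directional. The estimated FDR at $\Delta$ is the median,
across permutations, of the number of permuted $d$ values beyond the cutoffs,
divided by the number of genes called, capped at 1. An optional $\pi_0$
multiplier (default 1, i.e. off) can scale the estimate by the assumed
proportion of true nulls; with it off the estimate is conservative when many
genes are truly changed.

### Assumptions

- Values are already summarized to one number per probeset per array and are
  on a log scale where additive group effects are meaningful.
- Within-gene noise is exchangeable across arrays under the null, which is
  what label permutation requires. Systematic array-level shifts violate
  this, hence quantile normalization first.
- Groups are independent samples; there is no pairing structure.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `s0` in `sam()` | `"auto"` | log2 | grid over percentiles 0,5,…,100 of $s$; pick by flattest window-wise MAD of $d$ (coefficient of variation across 100 quantile windows of $s$); ties go to the smaller candidate |
| `B` | 1000 (200 in `run_pipeline`) | permutations | enumeration takes over automatically for small designs; 100–200 suffices for stable medians at the FDR levels used here |
| `fdr` | 0.05 and 0.1 | — | 5% for full-cohort contrasts, relaxed to 10% for the low-powered within-phenotype condition contrasts |
| `cutoff` | `"auto"`, fallback 4.0 | log2 | the dip of a kernel density (Sheather–Jones bandwidth) of per-gene mean intensities between the two highest peaks; 4.0 is the conventional floor for background-corrected bimodal intensity data |
| shift-test `method` | `"ranksum"` | — | rank-based and robust to the heavy tails of $d$; `"ks"` and `"perm"` (≥10,000 random same-size sets) are alternatives |
| shift-test `background` | `"exclude"` | — | the complement of the set; `"include"` compares against all genes instead |
| ORA universe | caller-supplied | — | should be the probesets that survived filtering (the tested background), not the whole platform |

## The synthetic cohorts

`sim_config()` defaults describe the emulated study design: four groups
AU-S/AU-NS/AI-S/AI-NS with 8/8/8/7 arrays (a 31-array aged-rat cohort after
one QC exclusion), a bimodal log2 intensity distribution with modes at 2.0
and 8.0 and 40% of genes in the low mode, gene-level means spread 0.8 around
their mode, gene SDs from a scaled inverse-chi-square-like family
(`base_sd * sqrt(shape / rchisq(shape))`, base 0.30 log2, shape 5 — enough
heterogeneity that $s_0$ selection is non-trivial), per-array additive
offsets of 0.1 log2, and 300 planted differentially expressed genes at 0.6
log2 (configurable per gene or in units of each gene's own SD). Planted
effects are placed only among high-mode genes, since low-mode genes are
removed before testing by design; the up/down split is configurable
(`de_up_fraction`, default 0.5 — set near 1 to mimic cohorts where increases
dominate). Where the emulated study did not state a quantity (noise
magnitudes, low-mode fraction, array-offset scale) the values above were
chosen once as typical of background-corrected two-channel-free microarray
data and are not re-tuned.

`generate_paired_datasets()` builds two cohorts whose planted gene sets share
exactly `round(cross_dataset_share * n_de)` members with equal-signed
effects; the dataset-specific remainders are drawn disjointly, so the shared
count is exact by construction and share 0 means fully dataset-specific
signatures. This is the device for validating cross-dataset concordance:
the Pearson correlation of paired d-statistics rises monotonically with the
shared fraction and sits inside the null envelope at share 0.

What the generator does *not* emulate: probe-level effects and GC-content
background structure (generation starts at summarized probesets),
correlation between genes (genes are independent given the array offset), and
heavy-tailed or intensity-dependent noise. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
additive-Gaussian regime, not robustness to every artifact of real arrays.
Each dataset consumes one RNG stream seeded from `config$seed`; paired
datasets derive per-dataset sub-seeds deterministically (documented in
`derive_seed()`), so all outputs are reproducible bit for bit.

## Numerical choices

- **Delta grid.** 101 quantiles of $|d_{(i)} - \bar d_{(i)}|$ plus the 500
  largest deviations individually. The tail resolution matters: with a
  quantile-only grid the achievable call sizes near 5–10% FDR jump by
  hundreds of genes and sensitivity is lost to grid coarseness.
- **Monotonized FDR.** The raw median-count estimate need not be
  non-increasing in $\Delta$; the `fdr` column enforces monotonicity by a
  running maximum from the largest $\Delta$ downward (raw values kept in
  `fdr_raw`). Calls at a target use the smallest $\Delta$ meeting it.
- **Ties and determinism.** Order statistics break ties by stable input
  order; enumeration makes small-design nulls seed-independent; sampled
  permutations are seeded explicitly. MDS/PCA axes fix reflections by making
  the largest-magnitude coordinate positive in each dimension.
- **Degenerate inputs.** Zero within-group variance with $s_0 = 0$ reports
  ±Inf with a warning; an all-equal scatter vector selects $s_0 = 0$ with a
  warning; a delta with zero calls reports FDR `NA`; a gene set spanning the
  whole background is an error for rank-sum/KS and $p = 1$ for the
  permutation method; shift tests refuse sets with fewer than 5 members
  present; concordance p-values are floored at 1e-300 and labelled
  `"<1e-300"`.
- **Filtering unit.** Genes are removed whole when their across-sample mean
  is strictly below the cutoff — per-gene, not per-value — because the
  d-statistic needs complete per-gene vectors and the bimodality is a
  per-gene phenomenon.
- **Outlier arrays.** Flagged when a sample's median inter-array Pearson
  correlation falls strictly below Q1 − 1.5·IQR of the per-sample medians,
  never more than 20% of samples. This replaces visual MDS/pseudoimage
  inspection with a reproducible rule.
- **MDS flavor.** Classical (Torgerson) scaling on `1 − r` distances:
  deterministic, exact on Euclidean-embeddable inputs, and negative
  eigenvalues are truncated with a logged magnitude.

## Design choices where the ground was open

- The distribution-shift test for gene sets is the Wilcoxon rank-sum against
  the complement by default. Extremely small reported p-values for large
  shifted sets are expected behavior of rank tests at these sizes, not
  overflow artifacts.
- Bonferroni correction for over-representation counts only the groups with
  non-zero universe overlap, and the hypergeometric tail includes the
  observed overlap, so a saturated query (query = universe) yields p = 1
  rather than 0.
- Permutation FDR uses the median permuted false-call count (not the mean),
  and $\pi_0$ correction is off by default; both choices make estimates
  conservative when a substantial fraction of genes is truly changed, because
  planted effects inflate the permuted null.

## Known limitations

- Power at these sample sizes is bounded by the per-gene degrees of freedom:
  with 8 arrays per group a gene shifted by twice its own SD is a noncentral
  t on 14 df (noncentrality 4), and no cutoff on such statistics can recover
  much more than ~73% of planted genes while keeping the realized false
  fraction under 10%. The $s_0$ offset reshapes the tails but does not add
  degrees of freedom; methods that shrink the variance itself (empirical
  Bayes moderation) are out of scope here. The acceptance script reports the
  measured sensitivity (~0.6 median at a 5% FDR target, with realized FDR
  ~0.03) so this ceiling is visible rather than hidden.
- The FDR estimate is an expectation-style estimate from permuted labels; in
  any single small cohort the realized false fraction varies around it.
- Quantile normalization assumes most genes are unchanged; with very large
  planted fractions (or real global shifts) it compresses true effects.
- Multi-class, paired, and survival designs are not supported; contrasts are
  strictly two-group (condition pooling is done by relabeling, e.g.
  phenotype-level contrasts pool S and NS arrays).

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 500–6,000 genes. The end-to-end
property checks use: 50-gene oracle comparisons; a 1,500-gene 3v3 design for
Monte-Carlo vs enumerated FDR (B = 2,000 vs all 20 assignments); 100
simulations of 5,000 genes (8v8, 250 planted effects, B = 100) for FDR
calibration; 20 simulations of 10,000 genes (300 planted) for recovery; 20
null cohorts × 50 random sets for shift-test size and 200 planted-shift
simulations for its power; paired 4,000-gene cohorts at shared fractions 0,
0.5 and 1; and a 1,500-gene pipeline determinism check. These sizes keep the
whole suite under a few minutes while leaving the Monte-Carlo error well
inside each check's tolerance.
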
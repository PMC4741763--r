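---
title: "Methods: cross-tissue invasiveness methylation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue invasiveness methylation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`methsig` analyzes the comparative design in which invasive cancer cell
lines from three tissues are each matched to a non-invasive line of the same
tissue and profiled on a 450K-style methylation array (beta values
β ∈ [0, 1], the methylated fraction per CpG) and an expression array.
Methylation changes shared by all three invasive lines — despite their
different tissue baselines — are taken as an invasiveness signature; tissue
identity and culture idiosyncrasies cancel in the three-way intersection.

The per-pair model is a two-group comparison on M-values,
M = log₂(β/(1−β)), with β clipped into [ε, 1−ε] (ε = 10⁻⁶ by default) so M
stays finite. Effects are reported as Δβ = β̄(invasive) − β̄(non-invasive)
on the beta scale, where the > 25% calling threshold is interpretable;
testing happens on the M scale, where variance is approximately constant
across the β range.

## The differential test

The original platform software computes probe-level p-values under a
proprietary bead-level error model that pools variance information across
the array. With 2–3 replicate cultures per line, that pooling is what makes
stringent thresholds reachable: a plain per-probe Welch t with 3 + 3
observations has ≈ 4 degrees of freedom, so even a large, clean effect
(|Δβ| = 0.4, M-scale noise SD 0.5, expected |ΔM| ≈ 3) sits near
t ≈ 7 where the per-probe two-sided p is around 2–4 × 10⁻³ — above a
p < 0.001 cut more often than below it. No per-probe test at n = 3 can
deliver both high recall at p < 0.001 and honest degrees of freedom.

`test_pair()` therefore defaults to the limma moderated t on M-values: an
empirical-Bayes compromise that shrinks per-probe variances toward a pooled
prior and adds the prior degrees of freedom to the residual ones — the
standard Bioconductor approach for exactly this design. The per-probe Welch
t (with Welch–Satterthwaite df and a 10⁻¹² variance floor against constant
groups) remains available as `method = "welch"` and is the test used by the
scalar `welch_t_test()`. Expression testing (`call_de_pair()`) makes the
same choice on log₂ intensities for the same reason.

DMP calling uses strict inequalities, |Δβ| > 0.25 and p < 0.001, on raw
p-values by default. Because "FDR-adjusted p < 0.05" is an equally common
convention, Benjamini–Hochberg q-values are always computed (our own
step-up implementation, cross-checked against `p.adjust` in the tests) and
`mode = "fdr"` switches calling to q < threshold. Neither mode is claimed
to be the uniquely correct one; both are exposed and the report records
which was used.

The DiffScore convention 10·sign(Δ)·(−log₁₀ p) is kept for both platforms
so that the familiar thresholds translate: |13| ↔ p ≈ 10⁻¹·³ ≈ 0.05,
|30| ↔ p = 0.001. Expression calls combine fold ≥ 2 (linear scale, on
quantile-normalized intensities, invasive/non-invasive orientation) with
DiffScore > 13.

## Enrichment and overlap statistics

Set-overlap and category-enrichment significance use the hypergeometric
upper tail, accumulated from log binomial coefficients with a log-sum-exp,
so log₁₀ p is exact even when p underflows double precision (array-scale
enrichments routinely reach p < 10⁻³⁰⁰). A binomial tail
(`log10_binomial_tail()`) covers the case where only a background fraction,
not a finite universe, is known. Both are verified in the tests against
exhaustive enumeration (all small-universe instances) and log-space
`pbinom`/`phyper`, and the binomial tail against its Chernoff/KL bound.

Universes are a genuine free choice in this design. Defaults: probe-level
tests use the probes tested in all three pairs; gene-level tests use genes
with at least one tested probe intersected with the expression platform's
features. Every report prints the universe actually used, and the
enrichment functions accept explicit universes.

For the three-way Venn significance no exact tail is standard, so
`multiway_overlap_significance()` draws seeded same-size random sets from
the universe and reports (b + 1)/(n + 1); the closed-form independence
expectation |U|·∏(|Sᵢ|/|U|) is reported alongside, and the k = 2 case is
cross-checked against the exact hypergeometric tail in the tests.

## Clustering

`cluster_samples()` uses 1 − Pearson correlation between sample profiles
with average linkage; neither setting is forced by the design, both are the
common defaults for methylation sample clustering, and both are arguments.
Missing values are handled pairwise-complete. Determinism relies on
`stats::hclust`'s lowest-index merge convention; trees export to Newick via
`ape`. The two-cluster cut is compared against the phenotype partition on
the signature probes — that is the claim the design supports. On the *full*
probe matrix the tissue signal can legitimately dominate and group samples
by tissue instead; the package does not assert full-matrix phenotype
clustering.

## The synthetic-data generator

`simulation_config()` defaults encode the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 20,000 | array size (desk-scale stand-in for 450K) |
| `tissues`, `replicates` | 3 tissues × 3 | invasive + non-invasive lines |
| `low_rep_tissue/n` | 3rd tissue, 2 | duplicate-culture non-invasive line |
| `n_common_hypo/hyper` | 300 + 300 | planted concordant CpGs |
| `n_tissue_specific` | 200/tissue | background DMPs, random direction |
| `effect_delta_beta` | 0.40 | planted \|Δβ\| (unitless beta fraction) |
| `noise_sd_m` | 0.5 | replicate noise SD, M (log₂) scale |
| `tissue_sd_m` | 0.8 | tissue deviation around the shared baseline |
| `enhancer_fraction` | 0.21 | array-wide enhancer prevalence |
| `enhancer_enrichment_in_hypo` | 0.47 | enhancer rate among planted hypo CpGs |
| `promoter_fraction` | 0.40 | probe-gene relations with 5′ labels |
| `concordance` | 0.8 | planted promoter-hypo genes made ≥2-fold up |
| `effect_lfc` | [1.5, 2.5] | planted expression log₂ fold change |
| `expr_noise_sd` | 0.25 | expression replicate noise, log₂ scale |

Generation model: each probe has a shared baseline beta drawn from a
bimodal mixture (components near 0.1 and 0.9 plus a small uniform part, the
typical array marginal); each tissue perturbs it by an M-scale Gaussian
deviation (`tissue_sd_m`), giving realistic cross-tissue correlation with
distinct tissue identities. Planted probes instead draw the unaffected
group's baseline uniformly over the range that keeps baseline and
baseline ± Δβ inside (0, 1) — drawing them from the extreme mixture
components would park every invasive signature value near 0.5 and erase the
probe-to-probe structure that sample clustering relies on. Replicates are
`logistic(M_groupmean + N(0, noise_sd_m))`, hence strictly inside (0, 1);
noise on the M scale reproduces the heteroscedasticity of betas near the
boundaries. Stage seeds (annotation, methylation, expression) derive from
the master seed by fixed offsets, and the generators restore the caller's
RNG state.

Expression: log-normal intensities around a per-gene baseline
(log₂ mean 7, SD 1.5 — HT12-like scan intensities); a `concordance`
fraction of the genes with a planted promoter-hypo CpG receives a log₂
fold change drawn from `effect_lfc` in the invasive samples of all three
tissues. The lower bound 1.5 keeps planted genes clearly above the two-fold
*calling* line after noise and quantile normalization rather than exactly on
it, which is the regime the validated candidates occupy (robust, several-fold
inductions); per-tissue background DE genes are added outside the planted
set.

What the generator does **not** emulate: Infinium I/II probe-type chemistry,
detection-p filtering, batch effects, copy-number interference, cell-type
mixtures, or correlated probes within CpG islands. Passing recovery tests
therefore demonstrate the pipeline's statistical behavior under the declared
noise model, not performance on raw GEO matrices; real inputs are assumed to
be pre-processed beta matrices with failed probes already removed.

## Numerical and degenerate-input choices

- Beta clipping ε = 10⁻⁶: bounds |M| ≈ 19.9 without moving interior betas.
- Variance floor 10⁻¹² per group in Welch; results touching it are flagged
  `degenerate` rather than silently returned.
- p-values are floored at the smallest positive double before DiffScore /
  q-value computation; tail p-values that underflow are reported as 0 with
  the exact `log10_p` alongside.
- NA tokens accepted in TSVs: empty, `NA`, `NaN`, `null` (case-insensitive).
  A probe is tested in a pair only with ≥ 2 non-missing values per group;
  otherwise it is excluded from that pair's universe and counted.
- Annotation positions are 1-based (manifest convention); the BED export is
  0-based half-open, single-base intervals, score = round(1000·|mean Δβ|).
- Quantile normalization ties receive the mean of the rank-range averages;
  the implementation is cross-checked against `limma::normalizeQuantiles`
  on tie-free input.
- The immunohistochemistry total score is additive: intensity (0–3) plus
  stained-proportion (0–7), range 0–10, matching observed score ranges up
  to 8.9.
- `pooled_t_from_summary()` reconstructs two-sample t-tests from printed
  (n, mean ± SD) triplets; with rounded inputs, agreement with published
  p-values is approximate by nature, and the tests assert consistency bands
  rather than equality.

## Problem sizes

The test-suite and acceptance runs use 20,000-probe simulations (five
seeds) for recovery checks and 4,000-probe replicates for clustering and
module tests — sizes at which every planted class is populated in the
hundreds, recovery metrics have small Monte-Carlo error, and the whole
suite completes in well under a minute on a laptop-class core. All
quantities scale to 450K-sized inputs through the same code paths.

## Known limitations

- The moderated test assumes exchangeable per-probe variances on the M
  scale; strong variance heterogeneity (e.g. probe-type effects) would make
  its shrinkage less appropriate than on the simulated data.
- Region-level (DMR) calling, cell-composition adjustment, and pathway
  analysis are out of scope.
- Published enrichment p-values from comparable analyses depend on
  unreported universe sizes and a proprietary differential test; this
  package reports its own universes explicitly, and count-level agreement
  with such analyses is expected only approximately (surrogate-test
  differences of ±15% on counts would not be surprising). The real-data
  path (`pipeline_config(paths = ...)`) exists precisely so such full-scale
  comparisons can be run when the deposited matrices are available locally.
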
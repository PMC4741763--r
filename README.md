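# methsig

Cross-tissue invasiveness methylation-signature analysis for Illumina
450K-style beta-value data.

## The problem

Invasive cancer cell lines from different tissues of origin (e.g. breast
MDA-MB-231 vs MCF7, liver SKHep1 vs HepG2, prostate PC3 vs LNCaP) differ
widely in their overall methylomes, yet may share a common methylation
program driving invasiveness. `methsig` implements the comparative design
that isolates that shared program:

1. **Per-pair differential methylation.** For each tissue, every CpG probe is
   tested invasive vs non-invasive. Effects are summarized as
   Δβ = β̄(invasive) − β̄(non-invasive) on the beta scale (β = methylated
   fraction ∈ [0,1]), while the test runs on M-values,
   M = log₂(β/(1−β)), the variance-stabilized scale. The default test is the
   limma empirical-Bayes moderated t (2–3 replicates per line give a plain
   per-probe test too few degrees of freedom); per-probe Welch is available.
   A probe is a DMP when |Δβ| > 0.25 and p < 0.001 (strict, both
   configurable; an FDR-based mode using Benjamini–Hochberg q < 0.05 is also
   provided). Scores follow the Illumina DiffScore convention
   10·sign(Δβ)·(−log₁₀ p), so |13| ≈ p 0.05 and |30| = p 0.001.
2. **Concordant intersection.** The signature is the set of CpGs hyper- (or
   hypo-) methylated in the invasive line of *all three* pairs, with the
   universe restricted to probes tested in all pairs. Venn-style overlap
   significance uses a seeded permutation test with a closed-form
   expectation cross-check, plus exact pairwise hypergeometric tails.
3. **Genomic-context enrichment.** Signature CpGs are collapsed to genes,
   filtered to 5′/promoter context (TSS1500, TSS200, 5′UTR, 1st exon), and
   tested for enhancer/promoter enrichment with a hypergeometric upper tail
   accumulated in log space — p-values far below the double underflow
   threshold are reported exactly via log₁₀ p.
4. **Expression integration.** Expression matrices are quantile-normalized;
   genes are called up/down per pair when fold ≥ 2 and DiffScore > 13; the
   overlap of promoter-hypomethylated with concordantly upregulated genes is
   tested hypergeometrically.
5. **Clustering.** Samples are clustered hierarchically (1 − Pearson
   correlation, average linkage) over the signature probes; trees export to
   Newick.

A synthetic-data generator plants a known cross-tissue signature (effect
size, noise, enhancer background, expression concordance all configurable)
so that every stage is verifiable against ground truth without downloads.

## Worked example

```r
library(methsig)

cfg <- simulation_config(n_probes = 10000, seed = 42)   # planted 300+300 CpGs
report <- run_pipeline(pipeline_config(simulation = cfg,
                                       n_permutations = 300, seed = 42),
                       out_dir = "run42")
print(report)
#> pipeline_report (seed 42): 294 common hyper / 290 common hypo CpGs;
#>   89 common up / 0 common down genes; hypo/up overlap 84 (log10 p = -144)

report$enrichment$enhancer_hypo[c("hits", "subset_size", "fold_enrichment")]
#> 134 of 290 hypo CpGs in enhancers (46.2% vs 21.0% background),
#> fold 2.20, log10 p = -21.8

report$recovery
#> $jaccard_common_hypo   0.967     # recovered vs planted CpG sets
#> $jaccard_common_hyper  0.980
#> $null_false_call_rate  0
#> $concordance_recovered 0.73      # hypo∩up genes / planted promoter-hypo genes

report$overlap$hypo
#> observed 290, expected 0.63 under independence, permutation p = 0.0033
```

Reading: of 10,000 probes the pipeline recalls the planted concordant sets
almost perfectly (Jaccard ≈ 0.97) with no false calls among null probes; the
planted 47% enhancer prevalence among hypomethylated CpGs is detected
against the 21% array background (fold 2.2); and 84 of the planted
promoter-hypomethylated genes are recovered as ≥2-fold upregulated in all
three pairs (hypergeometric log₁₀ p = −144). `run42/` contains the signature
BED file, gene lists, per-pair DMP tables, the Newick dendrogram, the
reordered heatmap matrix and a JSON report.

Real datasets enter through the same interface via
`pipeline_config(paths = list(beta = ..., annotation = ..., samples = ...,
expression = list(...)))` with plain TSV inputs (see `read_beta_matrix`,
`read_probe_annotation`, `read_sample_sheet`, `read_expression_matrix`).

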
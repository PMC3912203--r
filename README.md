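# bandenrich

Positional enrichment and coordinate-control analysis of dysregulated
transcriptomes.

## The problem

Bulk RNA-seq studies that compare two phenotype groups (for example,
airway basal cells of smokers versus nonsmokers) often find that the
differentially expressed genes are not scattered uniformly over the
genome but concentrate on particular chromosomes or cytogenetic subbands
— regions that may coincide with disease risk loci mapped by GWAS.
Turning that impression into a statistic requires care: gene density
varies enormously between regions, so "13 dysregulated genes on one
subband" is only meaningful relative to how many genes a random,
equally sized set drawn from the *expressed* genes would put there.

`bandenrich` implements that analysis end to end for FPKM expression
matrices with two phenotype groups (A = reference, B = comparison):

1. **Background threshold** — the expression-above-background cutoff is
   estimated as the intersection of two empirical curves over a
   candidate grid *t*: the false discovery rate
   FDR(*t*) = P(intergenic FPKM ≥ *t*) and the false negative rate
   FNR(*t*) = P(exonic FPKM < *t*). Genes with mean FPKM ≥ threshold
   across all samples are scored as expressed.
2. **Differential expression** — per gene, a Welch *t*-test on
   log₂(FPKM + 1), Benjamini–Hochberg step-up adjustment
   (q₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎·m/j), and a signed fold-change on the
   linear-scale group means with the negative-reciprocal convention
   (r = mean_B/mean_A reported as r if r ≥ 1, else −1/r). A gene is
   significant when |fc| > 1.5 (strict) and q < 0.05.
3. **Positional enrichment** — for each chromosome and subband, the
   observed count of significant genes is compared to a resampling
   null: 10⁴ draws of an equally sized gene set, sampled without
   replacement from the expressed universe minus the tested set. The
   add-one empirical p-value is
   p = (1 + #{null ≥ observed}) / (iterations + 1), upper-tail only.
   Resampling from the expressed universe makes the gene-density
   adjustment automatic.
4. **Coordinate control** — co-expression of a gene cluster within each
   group, summarised by the mean pairwise Pearson correlation (and the
   mean squared correlation) over all gene pairs, tested against random
   equally sized gene sets with the same permutation machinery.

A synthetic-data generator reproduces the statistical structure this
analysis assumes (log-normal FPKM, a planted DE set concentrated on a
chosen subband, a latent-factor-correlated gene module whose
correlation weakens in group B), so the whole pipeline is testable
without any external download.

## Worked example

Simulate a 4,000-gene study with the default design (10 vs 7 samples,
~5% planted DE genes over-assigned 5× to subband 19q13.2, a 13-gene
correlated module) and run every stage:

```r
library(bandenrich)
cfg <- pipeline_config(
  simulation = sim_config(n_genes = 4000, seed = 7),
  n_iterations = 2000, n_permutations = 1000, seed = 7,
  output_dir = "readme_run")
report <- run_pipeline(cfg)
print(report)
#> pipeline_report (bandenrich 0.1.0)
#>   expressed genes: 3995 of 4000 at threshold 0.0818 FPKM
#>   significant: 154 ( 146 up, 8 down )
#>   top chromosome: 19 (27 genes, 18%, p = 0.016)
#>   top subband: 19q13.2 (7 genes, 5%, p = 0.002)
#>   coordinate control: mean_r A = 0.639 (p = 0.000999), B = 0.095 (p = 0.121)
```

The threshold stage kept 3,995 genes whose mean FPKM cleared the
estimated 0.08 FPKM background cutoff. The DE stage called 154
significant genes, dominated by up-regulation in group B — the planted
asymmetry. The enrichment stage ranks locations by empirical p:

```r
print(report$enrichment$subband)
#> enrichment_result (subband level, 154 genes, 2000 iterations)
#>   location observed percent null_mean p_empirical
#> 1  19q13.2        7       5     1.796    0.001999
#> 2   Xp11.2        7       5     2.120    0.008496
#> 3  16p11.2        5       3     2.428    0.083958
```

The planted subband 19q13.2 carries 7 of the 154 significant genes
(5%) against a null expectation of 1.8 — empirical p ≈ 0.002 at 2,000
iterations. Finally, the coordinate-control stage takes the significant
genes on that subband as the focus cluster and contrasts its
co-expression between groups:

```r
print(report$coordinate$A)
#> correlation_summary: group A - 7 genes
#>   mean_r = 0.639  mean_r2 = 0.489  squared_mean_r = 0.409
#>   permutation p (mean_r, 1000 permutations) = 0.000999
```

Group A's mean pairwise correlation of 0.64 is higher than every one of
1,000 random gene sets (p = 1/1001), while group B (mean r = 0.10,
p = 0.12) is indistinguishable from chance — the planted loss of
coordinate control.

All stage outputs (DE table, enrichment tables, correlation matrices,
PCA scores, a JSON manifest with every parameter and seed) are written
under `output_dir`; re-running with the same seed reproduces them byte
for byte.

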
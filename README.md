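# metaxes

Dissecting heterogeneity in multi-ancestry genome-wide association
studies (GWAS).

When hundreds of GWAS spanning several continental ancestry groups are
combined, allelic effects at disease-associated variants often differ
between studies. `metaxes` asks *why*: how much of that heterogeneity
tracks genetic ancestry, which biological pathways the associated
variants act through, and whether pathway-specific genetic burden carries
distinct clinical consequences. It is aimed at statistical geneticists
analysing summary-level multi-ancestry meta-analyses (type 2 diabetes is
the motivating disease), and it ships a synthetic-data generator so the
entire pipeline runs — and its tests pass — without access to consortium
data.

## The model at the core

For one variant with per-study log-ORs $b_k$, standard errors $s_k$ and
weights $w_k = 1/s_k^2$, effects are regressed on $T$ axes of genetic
variation $x_{tk}$ (principal coordinates of the between-study
allele-frequency distance matrix):

$$E(b_k) = \beta_0 + \textstyle\sum_t \beta_t x_{tk}.$$

Writing RSS for the weighted residual sum of squares, three chi-square
statistics partition the weighted variation: **association**
($\sum w_k b_k^2 - \mathrm{RSS}_{full}$, $1+T$ df),
**ancestry-correlated heterogeneity**
($\mathrm{RSS}_{intercept} - \mathrm{RSS}_{full}$, $T$ df) and
**residual heterogeneity** ($\mathrm{RSS}_{full}$, $K-1-T$ df); the two
heterogeneity parts sum exactly to Cochran's $Q$. Around this core the
package provides LD clumping into signals and loci, k-means clustering of
index variants on sample-size-corrected trait z-scores
($Z_{ij} = \beta_{ij}/(\sqrt{N_i}\, s_{ij})$) with iterative imputation of
missing values, Firth bias-reduced logistic regression for cell-type
open-chromatin enrichment ($\theta$ = log fold enrichment, penalized LRT),
and cluster-partitioned polygenic scores tested against outcomes per
ancestry group and pooled by DerSimonian–Laird random effects. Details
and design rationale are in the methods vignette
(`vignettes/metaxes-methods.Rmd`).

## Worked example

A seeded end-to-end run on synthetic data: 250 variants, 10 studies in
three ancestry groups, 25% of variants causal with a slope of 0.5 on the
first ancestry axis, three planted mechanistic clusters.

```r
library(metaxes)

cfg <- sim_config(n_snvs = 250, b0 = 0.08, causal_fraction = 0.25,
                  n_studies_per_group = c(EUR = 4L, EAS = 3L, AFA = 3L),
                  group_fst = c(EUR = 0.02, EAS = 0.12, AFA = 0.15),
                  n_axes_true = 2, axis_effects = c(0.5, 0),
                  n_clusters_true = 3, n_haplotypes = 300, seed = 1)
run <- run_pipeline(pipeline_config(sim = cfg, n_axes = 2, k = 3,
                                    ps_n = 2000,
                                    ps_ancestries = c("EUR", "EAS")))
run$report$heterogeneity
#> # A tibble: 1 × 7
#>   threshold n_anc_het pct_anc_het p_anc_binom n_res_het pct_res_het p_res_binom
#>       <dbl>     <int>       <dbl>       <dbl>     <int>       <dbl>       <dbl>
#> 1    0.0017        26        86.7    1.60e-68         0           0           1
```

The pipeline found 30 independent signals; at the Bonferroni threshold
for 30 signals (0.05/30, shown rounded to two significant figures), 26
show ancestry-correlated heterogeneity — as planted, since causal-variant
effects rise along axis 1 — while none shows residual heterogeneity, and
the one-sided binomial P confirms the excess over the ~1.5 signals
expected by chance.

```r
dplyr::filter(run$enrichment, significant)[, c("cluster", "cell_type", "theta", "p")]
#> # A tibble: 2 × 4
#>   cluster cell_type          theta        p
#>   <chr>   <chr>              <dbl>    <dbl>
#> 1 2       enriched_celltype   1.88 1.56e-2
#> 2 3       enriched_celltype   3.28 4.04e-4

run$ps_pooled[, c("score", "estimate", "se", "p")]
#> # A tibble: 4 × 4
#>   score     estimate     se      p
#>   <chr>        <dbl>  <dbl>  <dbl>
#> 1 cluster_1   0.193  0.0906 0.0328
#> 2 cluster_2  -0.130  0.0709 0.0666
#> 3 cluster_3  -0.0680 0.0578 0.239
#> 4 overall     0.102  0.0733 0.165
```

Only the planted cell type reaches the per-set Bonferroni threshold, and
the partitioned polygenic score recovers the planted log-OR of 0.2 per SD
on cluster 1's score (0.193 ± 0.091, pooled over two ancestry groups),
while the overall score's association is diluted — the argument for
partitioning. Each result is also written as a tab-delimited table (plus a
YAML run manifest with per-file checksums) when `run_pipeline()` is given
an `outdir`.

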
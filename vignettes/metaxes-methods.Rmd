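---
title: "Dissecting ancestry-correlated heterogeneity in multi-ancestry GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting ancestry-correlated heterogeneity in multi-ancestry GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`metaxes` implements an analysis chain for multi-ancestry genome-wide
association studies (GWAS) of a complex disease such as type 2 diabetes:

1. **Axes of genetic variation** — low-dimensional study coordinates from
   multidimensional scaling of allele-frequency distances between studies.
2. **Meta-regression** of per-study allelic effects on those axes, with a
   partition of between-study heterogeneity into an ancestry-correlated
   component and a residual component.
3. **Signal and locus definition** — greedy LD clumping of genome-wide
   significant variants into independent signals and merging of index
   variants into loci with novelty flags.
4. **Mechanistic clustering** of index variants on sample-size-corrected
   cardiometabolic trait z-scores, by k-means with iterative imputation of
   missing values.
5. **Cell-type open-chromatin enrichment** per cluster, by Firth
   bias-reduced logistic regression with a penalized likelihood-ratio test.
6. **Cluster-partitioned polygenic scores** tested against clinical
   outcomes per ancestry group and pooled by random-effects meta-analysis.

Because the consortium-scale inputs such an analysis consumes (hundreds of
GWAS, millions of samples) are not redistributable, the package ships a
synthetic-data generator that emulates the statistical structure of every
input, so the full pipeline runs, and is tested, end to end from a single
seed.

# The meta-regression model and its heterogeneity partition

For one variant, let $b_k$ and $s_k$ be the log-odds-ratio estimate and
standard error in study $k = 1, \dots, K$, and let $x_{tk}$ be study $k$'s
coordinate on axis $t$. The model is a weighted linear regression

$$E(b_k) = \beta_0 + \sum_{t=1}^{T} \beta_t x_{tk}, \qquad w_k = 1/s_k^2,$$

with the standard errors treated as fixed (the usual inverse-variance
convention for summary statistics). Writing $\mathrm{RSS}(M)$ for the
weighted residual sum of squares of model $M$:

* **association**: $\sum_k w_k b_k^2 - \mathrm{RSS}(\text{full})$ on
  $1 + T$ df — does the variant affect disease risk, allowing effects to
  vary along the axes;
* **ancestry-correlated heterogeneity**:
  $\mathrm{RSS}(\text{intercept}) - \mathrm{RSS}(\text{full})$ on $T$ df —
  does the effect vary *with* the axes;
* **residual heterogeneity**: $\mathrm{RSS}(\text{full})$ on $K - 1 - T$
  df — leftover between-study variation.

The two heterogeneity statistics sum exactly to Cochran's $Q$ of the
intercept-only fit; this identity is enforced to $10^{-8}$ relative
tolerance in the test suite. With $T = 0$ the machinery reduces to
ordinary fixed-effects inverse-variance meta-analysis, which the package
also exposes directly (`fixed_effects_meta()`), both overall and within
ancestry groups (the within-group pooled log-ORs later become polygenic
score weights).

When study-level mean BMI in cases and controls is available,
`bmi_adjusted_meta()` moves the two BMI columns into the baseline of the
heterogeneity contrast, so the ancestry-correlated test compares
(intercept + BMI) against (intercept + BMI + axes), still on $T$ df. This
asks how much of the apparent ancestry-correlated heterogeneity is carried
by systematic BMI differences between study populations.

## Axes of genetic variation

The distance between two studies is the mean absolute difference of
effect-allele frequencies over variants reported in *all* studies, after
aligning alleles to a common reference orientation (mean squared difference
is available as an option). Classical multidimensional scaling —
double-centring of squared distances and eigendecomposition — yields the
coordinates. We use standard principal coordinates (eigenvectors scaled by
the square root of their eigenvalues, as `stats::cmdscale()` returns):
this is the scaling under which the coordinates reproduce the distance
matrix as well as any rank-$T$ approximation can, and every downstream
regression statistic is invariant to affine rescaling of the covariates,
so the choice has no inferential consequence.

Strand-ambiguous (A/T, C/G) variants are excluded from alignment by
default, because their orientation cannot be verified from the alleles
alone; the exclusion is logged and configurable.

## Genomic control

P values are converted to 1-df chi-square quantiles and
$\lambda_{GC}$ is their median over the null median
$\chi^2_1(0.5) \approx 0.456$, reported to three decimals. Multi-df
meta-regression tests are placed on the 1-df scale through their P values;
conventions differ between tools here, and this one has the virtue of
being well-defined for any test.

# Signals, loci and novelty

Clumping follows the standard greedy procedure: rank variants with
$P < 5 \times 10^{-8}$ by ascending P (ties broken by chromosome,
position, then alleles, so results are identical across platforms); each
still-unassigned variant becomes an index, and unassigned significant
variants strictly within 5 Mb of the index with $r^2 > 0.05$ in *at least
one* continental reference panel join its clump. Distance is measured from
the index only. $r^2$ is the squared correlation of haplotype allele
indicators in the reference panel — haplotype, not genotype, correlation,
matching reference-panel usage.

Index variants separated by strictly less than 1 Mb chain into one locus
(single linkage, so merging is transitive), and locus bounds extend 500 kb
beyond the extreme index positions, floored at position 1. A locus is
"previously reported" iff any known variant position falls inside its
closed bounds.

# Mechanistic clustering

## Sample-size-corrected z-scores

For index variant $j$ and trait $i$ with effect $\beta_{ij}$, standard
error $s_{ij}$, and maximum GWAS sample size $N_i$:

$$Z_{ij} = \frac{\beta_{ij}}{\sqrt{N_i}\, s_{ij}},$$

after sign-aligning $\beta_{ij}$ to the disease risk allele (the allele
with positive pooled fixed-effects log-OR). The $\sqrt{N_i}$ factor
removes the trivial dependence of z-scores on study size, so traits with
very different GWAS scales become comparable. Unreported pairs are
missing; so are pairs whose risk allele matches neither reported trait
allele (logged). We do not re-standardize columns before clustering — the
sample-size correction already places them on a common scale — but a
configuration switch exists for users who prefer unit-variance columns.

## k-means with iterative imputation

Missing z-scores are imputed inside the clustering loop rather than
beforehand:

* iteration 1 draws each missing entry from its phenotype's marginal
  empirical distribution (resampling observed values — no parametric
  assumption) and runs Lloyd's k-means, taking the best of 5 k-means++
  starts by within-cluster sum of squares;
* later iterations redraw missing entries from the empirical distribution
  of the entry's phenotype *within the variant's current cluster*, so
  between-phenotype correlation enters through the cluster conditioning;
* a penalty on imputed values decays linearly from 1 (iteration 1) to 0
  (iteration `n_end`, default 8 of `n_iter = 10`): imputed entries are
  multiplied by one minus the penalty when computing distances and
  centroids, so early, poorly-informed imputations carry little weight and
  the final iterations use imputed values in full;
* after the outer loop, a few penalty-free stabilization passes re-assign
  each variant to its nearest centroid measured on its *observed*
  coordinates only (mean squared distance over non-missing phenotypes),
  re-impute conditional on that assignment, and recompute centroids. A
  single random imputation draw would otherwise inject assignment noise
  exactly at the step that matters most; assigning on observed coordinates
  removes it, and in simulations this recovers planted partitions at 30%
  missingness nearly as well as an oracle that knows the true centroids.

With no missing entries, every imputation step is a no-op and the whole
procedure is identical to plain Lloyd k-means under the same seed — an
identity the test suite checks bitwise. Emptied clusters are re-seeded at
the farthest point and logged.

## Choosing k

`select_k()` fits every candidate $k$ and lets a battery of eight
validity indices vote by their native rules: Calinski–Harabasz (max),
mean silhouette width (max), Davies–Bouldin (min), Dunn (max), C-index
(min), gap statistic (one-SE rule with a uniform box reference), Hartigan
(smallest $k$ with statistic ≤ 10), and Krzanowski–Lai (max). The modal
vote wins, ties to the smaller $k$. Larger batteries (e.g. the 27 indices
of the NbClust package) are common in this field, but several of those
indices are redundant (monotone transforms of the same quantity) or
underspecified, so we ship a curated list with the same majority rule —
the list is configurable, and the majority-vote semantics are what
matters.

## Cluster profiles and follow-up tests

Phenotype profiles come from the no-intercept indicator regression
$E(Z_{ij}) = \sum_k \gamma_{ik} C_{jk}$, so $\gamma_{ik}$ *is* the
within-cluster mean of the imputed z-scores (an identity tested to
$10^{-10}$), with P values from the coefficient t-test and the heat-map
"temperature" defined as $\mathrm{sign}(\gamma)(-\log_{10} P)$. Euclidean
distances to centroids $\delta_{jk}$, a principal-components view of the
imputed matrix, an inverse-variance-weighted regression of
risk-aligned disease log-ORs on cluster indicators (heterogeneity tested
by the weighted deviance difference against an intercept-only fit,
chi-square on $k - 1$ df), and per-axis ANOVAs of axis z-scores across
clusters complete the cluster-level toolkit. Coefficient standard errors
in the weighted disease-effect regression stay on the known-weights
(inverse-variance) scale rather than being rescaled by residual
dispersion, for consistency with the meta-analysis conventions elsewhere
in the package.

# Cell-type enrichment

For each index variant, "null" variants lie within 50 kb (inclusive) and
show $r^2 \le 0.05$ with the index in *every* continental panel — a single
panel above the threshold excludes the candidate. Null pools are
deduplicated per cluster (a variant serving several indexes counts once);
by default a null variant is not excluded for falling inside another
signal's clump, though this is configurable.

Coding index variants 1 and null variants 0, the model is

$$\mathrm{logit}\, P(Y_j = 1) = \alpha_0 + \alpha_{\mathrm{EXON}} G^{\mathrm{EXON}}_j
 + \alpha_{\mathrm{3UTR}} G^{\mathrm{3UTR}}_j + \alpha_{\mathrm{5UTR}} G^{\mathrm{5UTR}}_j
 + \theta_i X_{ij},$$

fitted by Firth bias-reduced logistic regression: Newton iterations on the
Jeffreys-prior-penalized likelihood
$\ell(\beta) + \tfrac12 \log \det I(\beta)$, with the hat-diagonal
modified score, step-halving so the penalized likelihood never decreases,
and convergence at a $10^{-8}$ coefficient change. The penalty keeps
$\hat\theta$ finite under complete separation — essential for small
clusters and rare cell types. In the 2-by-2 case with no genic covariates
the estimate reduces to the Haldane-corrected log odds ratio
(add ½ to each cell), which the tests exploit as a closed-form oracle.

The enrichment test compares the full fit against a *constrained* fit with
$\theta_i = 0$ — crucially, the constrained fit keeps the full design's
Jeffreys penalty (only the coefficient is pinned at zero), and twice the
penalized log-likelihood difference is referred to $\chi^2_1$. Dropping
the tested column from the penalty as well systematically inflates the
statistic (the determinant term changes dimension), which simulation
shows is badly anti-conservative; the constrained formulation is
calibrated (type-I error within binomial noise of 5% over 2,000 null
replicates in the acceptance suite). Intervals are stored 0-based
half-open (BED); variant positions are 1-based; the conversion is made in
exactly one place and property-tested at the boundaries. Clusters with
fewer than 5 signals are skipped — parameter estimates from 3-signal
clusters are unstable — and Bonferroni thresholds use the size of the
cell-type set being scanned.

# Partitioned polygenic scores

Index variants failing quality control are excluded: minor allele
frequency below 1%, imputation quality $r^2 < 0.7$, or Hardy–Weinberg
exact P below $10^{-6}$ (the exact conditional test over heterozygote
counts, implemented from the standard recurrence and validated against
full enumeration). Each surviving variant carries its cluster label and
its ancestry-specific pooled log-OR as weight; dosages are aligned to the
risk allele (missing dosages mean-imputed per variant), raw cluster scores
are summed weights-times-dosages, and by construction the raw overall
score is the sum of the raw cluster scores. Each score is standardized to
mean zero and unit variance *within the analysis cohort* — and within the
analysis subset when an analysis restricts to cases only — so effects read
per SD of score in the population actually analysed.

Outcome models are generalized linear models (logistic for binary
outcomes, linear for age of onset) of the outcome on one cluster score at
a time, adjusted for the overall score and covariates; the overall-score
model omits cluster terms. Under separation the logistic fit falls back to
the package's Firth estimator, flagged in the output. Note that with the
overall-score adjustment, a genuine effect on one cluster induces
compensating non-zero coefficients on the others (the overall score is the
clusters' sum); the planted-truth recovery tests therefore check the
coefficient of the cluster that carries the effect, whose estimand equals
the planted value because the true predictor lies in the fitted span.
Ancestry groups are pooled by DerSimonian–Laird random-effects
meta-analysis (moment estimator of $\tau^2$, floored at zero), with
`metafor` serving as an independent cross-check in the tests.

# The synthetic-data generator

The generator emulates, structurally, every input the pipeline needs:

* **Haplotype panels**: ancestral allele frequencies uniform on
  $[0.05, 0.95]$; group frequencies Balding–Nichols,
  $f \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, with per-group $F$
  defaulting to a plausible continental spread (0.02–0.15). LD is
  block-wise: within a block each haplotype carries one latent uniform
  that each variant copies with probability `ld_within` (default 0.9),
  giving exact Balding–Nichols marginals, within-block correlation, and
  independence across blocks — enough structure for clumping and null-SNV
  selection without pretending to be a recombination map.
* **Study summaries**: per-study frequencies near the group's panel
  frequencies; latent study coordinates defined as the multidimensional
  scaling of the realized frequency-distance matrix, so planted axis
  slopes are recoverable without rotation ambiguity; true effects linear
  in the axes (optionally in study mean BMI); observed effects Gaussian
  with $s = 1/\sqrt{2f(1-f)N_{\mathrm{eff}}}$, the binary-trait
  approximation that matches inverse-variance weighting. Effective sample
  sizes are uniform on a configurable range (5,000–50,000 by default; the
  real distribution is a property of the assembled consortium, not of the
  method). A `causal_fraction` knob makes only a subset of variants carry
  effects, so the rest form realistic null pools.
* **Trait z-scores**: $Z_{ij} \sim N(\mu_{c(j),i}, 1)$ around planted
  centroids, masked missing completely at random (the real missingness
  mechanism is uncharacterized; MCAR is the neutral choice). A consistent
  table of raw betas and SEs is emitted alongside so the z-score
  computation itself is exercised.
* **Annotations**: peaks hit index variants with probability $p_1$ and
  null variants with $p_0$ in the designated enriched cell type, so the
  planted log fold enrichment is
  $\theta = \log[p_1(1-p_0)/(p_0(1-p_1))]$; other cell types use $p_0$
  throughout; genic intervals land independently of index status.
* **Cohorts**: dosages $\mathrm{Binomial}(2, f)$, logistic outcomes
  loading planted log-ORs on standardized cluster scores plus age and sex,
  and a linear age-of-onset channel.

Everything derives from one integer seed through per-stage hashed
sub-seeds, so each stage's stream is independent yet the whole run is
byte-reproducible.

**What the generator does not emulate** — realistic human LD maps and
recombination hotspots, allele-frequency ascertainment of genotyping
arrays, biobank recruitment bias, cryptic relatedness, and the X
chromosome. Passing tests on this synthetic world therefore demonstrate
that the estimators are implemented correctly and are calibrated under
the stated generative assumptions, not that those assumptions hold in any
particular real dataset.

# Numerical choices and degenerate inputs

* Weighted least squares via QR; singular designs (collinear axes or
  covariates, constant BMI columns) are detected at the rank check and the
  variant skipped with a logged reason.
* Heterogeneity statistics floored at 0 against roundoff; P values from
  the chi-square upper tail.
* Presentation rounding of reported thresholds uses two significant
  figures with ties away from zero (0.05/8 = 0.00625 prints as 0.0063);
  raw values are kept internally.
* P-value ties in clumping break lexicographically; monomorphic variants
  have undefined $r^2$ in that panel and are excluded from the
  max-over-groups (an error only if undefined everywhere).
* The Firth fitter flags non-convergence and returns the last iterate;
  the LRT statistic is floored at 0.
* Zero-variance scores (e.g. all weights zero after QC) are an error
  naming the offending cluster.

# Problem sizes

The test and acceptance suites run at deliberately desk-sized scales —
hundreds of variants, tens of studies, thousands of individuals, 2,000
replicates for calibration checks — chosen so the full suite completes in
minutes while keeping Monte-Carlo error well inside the asserted
tolerances (binomial-SD bounds are computed from the replicate counts
actually used).

# Known limitations

* Only autosomal, bi-allelic variants; no conditional analysis for
  secondary signals within loci, no fine-mapping.
* The heterogeneity partition treats SEs as known; very small studies
  violate this more than the inverse-variance convention usually tolerates.
* The cluster count vote is only as good as its index battery on
  non-spherical clusters; k-means itself assumes roughly isotropic
  clusters in z-score space.
* Random-effects pooling across ancestry groups uses DerSimonian–Laird,
  which is known to undercover with very few groups; with the typical
  five groups the pooled intervals should be read accordingly.
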
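---
title: "Partitioning trait variance between host genetics and the microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variance between host genetics and the microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbiability)
```

## The problem

Egg production in laying hens — summarized as EN300, the number of eggs laid
by 300 days of age — varies substantially between birds of a single flock.
Two candidate sources of that variation are the host genome and the
microbial communities of the digestive tract (crop, gizzard, small
intestine) and the reproductive tract (vagina, uterus, isthmus). This
package implements the statistical machinery for asking, in one cohort with
genotypes, per-site OTU tables and a phenotype, how much trait variance
each source explains, and which individual taxa carry the signal.

The design this package targets is a flock of 128 birds sampled at 6 body
sites (768 microbiome samples), with whole-genome SNP genotypes and one
EN300 record per bird.

## Models

### Relationship matrices

Host-genetic similarity between birds $i$ and $j$ is the genomic
relatedness matrix (GRM) built from reference-allele counts $r_{ia} \in
\{0,1,2\}$:

$$ h_{ij} = \frac{1}{N}\sum_{a=1}^{N}
   \frac{(r_{ia}-2\bar f_a)(r_{ja}-2\bar f_a)}{2\bar f_a(1-\bar f_a)}, $$

with $\bar f_a$ the sample frequency of the reference allele. Note the
coding: this counts **reference** alleles, the opposite of the ALT-dosage
most VCF tooling reports; `read_vcf()` performs the conversion.

Microbial similarity at body site $t$ is the microbial relationship matrix
(MRM) over abundances $a_{tio}$ of the $N_T$ OTUs observed at that site:

$$ r_{tij} = \frac{1}{N_T}\sum_{o=1}^{N_T}
   \frac{(a_{tio}-\bar a_{to})(a_{tjo}-\bar a_{to})}{\sigma^2_{to}}, $$

i.e. the mean cross-product of per-OTU standardized abundances.
`compute_mrm()` standardizes with the population variance (divisor $n$),
which forces the mean diagonal to be exactly 1; a sample-variance switch is
provided because the variance convention is ambiguous in practice, and both
raw (rarefied) counts and relative abundances are supported as the
abundance scale.

### Variance components

Heritability and microbiability are estimated from two single-random-effect
mixed models,

$$ \textbf{[A]}\quad y = Xc + g + e,\quad g \sim N(0, G\,\sigma^2_A)
   \qquad
   \textbf{[B]}\quad y = Xc + m + e,\quad m \sim N(0, M\,\sigma^2_m), $$

with $G$ the GRM and $M$ one site's MRM. The reported ratios are
$h^2 = \sigma^2_A/(\sigma^2_A+\sigma^2_e)$ and
$m^2 = \sigma^2_m/(\sigma^2_m+\sigma^2_e)$. Because each model has exactly
one structured random effect plus residual, restricted maximum likelihood
can be computed exactly in the eigenbasis of the relationship matrix
(`reml_single_component()`): the matrix is eigendecomposed once and the
restricted likelihood is profiled over the ratio
$\lambda = \sigma^2_u/\sigma^2_e$ on a log grid (61 points over
$10^{-5}..10^5$) followed by bounded refinement. This spectral form is the
EMMA device; no iterative multi-component solver is needed. Standard errors
of the ratio come from the delta method on the inverse average-information
matrix at the optimum; significance is a likelihood-ratio test against
$\sigma^2_u = 0$ with the boundary mixture null
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Ratio estimates live on the closed
interval $[0, 1]$; a profile maximized at the lower boundary reports
exactly 0.

Fixed covariates follow the study's convention: model [A] uses an intercept
plus the top 5 genotype principal components; model [B] additionally uses
the first 2 principal components of SNPs that reach $p < 10^{-6}$ in an
EMMAX-style mixed-model association scan (`lmm_gwas_scan()`, which fits the
variance ratio once under the null and tests each SNP by generalized least
squares — a standard, documented approximation to per-SNP ratio
re-optimization). When no SNP reaches the threshold the covariate block is
empty, with a warning.

Model [B] deliberately omits a genetic random effect, mirroring the
two-model design; residual genetic confounding beyond the SNP-PC covariates
is a scientific caveat, not something the estimator hides — the covariate
blocks are arguments, so `estimate_m2()` can be run with and without them
as a diagnostic.

### Community statistics

Diversity and community-difference statistics use the field's standard
definitions: rarefaction to the minimum sample depth, observed OTUs,
bias-corrected Chao1, ACE (rare threshold 10), Shannon entropy in log base
2 (the amplicon-toolchain default; a `base` switch is provided), the
Gini-Simpson index $1-\sum p_i^2$, Good's coverage, Bray-Curtis
dissimilarity, unweighted and **normalized** weighted UniFrac (both bounded
in $[0,1]$), and classical PCoA with negative eigenvalues reported but
excluded from explained-variance fractions. ANOSIM uses Clarke's statistic
with divisor $n(n-1)/4$ and mid-ranked ties; the Mantel test is two-sided
(permuted $|r|$), since signed correlations with significance are what the
analysis reports. All permutation p-values use the add-one convention
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$ and an explicit seed.

### Taxon screens

Two screening procedures operate per site, on the rarefied table:

* **Heritability screen** (`taxon_heritability_screen()`): each taxon's
  prevalence assigns its analysis mode — below 20% excluded; at least 20%
  but below 60% dichotomized to presence/absence (fit on the observed 0/1
  scale; no liability transform is applied, since none is standard here);
  60% or above analyzed as a standardized quantitative trait. Significance
  of the taxon's variance component is the REML LRT. A rank test is
  sometimes named for this purpose in the field, but a rank test does not
  address a variance component, so the LRT is used and the divergence is
  documented rather than guessed around.
* **Trait-association screen** (`en300_microbe_screen()`): a taxon passes
  only if (1) Wilcoxon rank-sum of its abundance between the bottom- and
  top-20% phenotype groups has raw p and BH-FDR below 0.05, (2) the
  BH-adjusted Pearson and (3) Spearman correlations with the phenotype are
  both significant. BH adjustment is performed within one (site, level)
  family — the scope matching how screen counts are reported per level.
  Extreme groups take `floor(0.2 n)` birds from each tail with ties broken
  by bird ID, so the grouping is deterministic.

## The simulator and what it does (not) emulate

Every estimator above is exercised against `simulation_truth()` /
`simulate_genotypes()` / `simulate_otu_table()` / `simulate_phenotype()`,
which generate data with known ground truth at the study's design points.
Choices that matter:

* **Flock structure.** Birds form full-sib families (default size 8 — near
  the information optimum for estimating an intraclass correlation of
  $h^2/2 \approx 0.14$), produced by gene dropping from unobserved parents.
  A single-hatch experimental flock is related, and without relatedness a
  128-bird cohort carries almost no information about $h^2$.
* **Composition.** Per-site log-mean abundance vectors (sd 1 across taxa)
  give each site its own composition; bird-level noise has a rank-3 shared
  "community state" factor (half the noise variance) plus idiosyncratic
  variation. Counts are multinomial at log-normal depth (median 50k reads,
  modest spread). Depth and evenness defaults are chosen so that
  multinomial sampling noise stays a minor share of per-taxon abundance
  variance even after rarefaction — otherwise the generative variance
  shares would not be estimable by any abundance-based model. Real 16S
  rank-abundance curves are more skewed than this; the generator is a
  statistical stand-in, not a fitted error profile (no chimeras, taxonomy,
  or read-level noise), so passing tests demonstrate estimator
  correctness, not robustness to every property of real amplicon data.
* **Planted signals.** A minority of taxa get a polygenic host-genetic
  component of latent log-abundance (default genetic share 0.8); an
  oligogenic switch (`snps_per_taxon`) exists, with the caveat that
  GRM-based heritability of a sparsely driven taxon is attenuated by
  imperfect tagging. Trait-associated taxa form a correlated guild (a
  shared community factor entered with per-taxon signs), the way
  co-occurring trait-associated taxa behave in real communities; this also
  makes "strong association" well-defined — with five fully independent
  taxa the per-taxon correlation is capped at $\sqrt{m^2/5}$, too weak to
  survive a 300-taxon FDR family.
* **Exact shares.** The phenotype's genetic, microbial and residual
  components are orthogonalized and rescaled so realized population
  variance shares equal the requested $h^2$ and $m^2$ exactly; the
  microbial effect acts through per-OTU standardized abundances, matching
  the MRM standardization, so $m^2$ is well-defined under model [B]. The
  EN300 scale (mean 75.32, sd 17.5, clipped to [24, 129]) is opt-in because
  clipping — though it touches well under 1% of draws — would otherwise
  perturb the exact variance arithmetic used by estimator tests.

## Numerical and procedural choices

* Genotype QC order is fixed — individuals by call rate, then SNPs by call
  rate, minor allele frequency (exact boundary: MAF must exceed the
  threshold) and the exact Hardy-Weinberg test (no mid-p) — and remaining
  missing calls are mean-imputed per SNP, which preserves allele
  frequencies and keeps the GRM defined for every bird.
* LD pruning (50 kb windows, 10-SNP steps, $r^2 > 0.2$, lower-MAF SNP
  removed, ties to the later position) is exposed but **not** applied
  before the GRM or PCA by default, following the convention of computing
  both from all QC-passing SNPs.
* Rarefaction draws without replacement to the minimum sample depth with a
  recorded seed; α-diversity is computed after rarefaction on the
  unfiltered table, and the ≥20% prevalence filter (inclusive, per site,
  unioned across sites) is applied before community and screen analyses.
* Degenerate inputs fail loudly rather than silently: all-tied distances
  (ANOSIM), constant matrices (Mantel), zero-variance taxa (correlations,
  extreme-abundance grouping), all-zero samples (diversity), monomorphic
  SNPs reaching the GRM, and an identity-like relationship matrix (for
  which the variance ratio is unidentifiable) are all errors with the
  offending item named.

## Problem sizes and what the tests measure

The shipped test-suite simulations use the package's study design at desk
scale: heritability recovery at $n = 200$ birds and 2,000 SNPs over 50
replicates (mean $\hat h^2$ within $\pm 0.05$ of 0.3); microbiability
recovery at $n = 128$ and 500 OTUs over 50 replicates (mean $\hat m^2$
within $\pm 0.05$ of 0.9, and the driving site beats a decoy site in at
least 90% of replicates); type-I error of every permutation/Z test within
[0.03, 0.07] over 1,000 null datasets at 999 permutations; and both taxon
screens against planted signals among 300 taxa.

A caution for interpreting any **single** run at the study scale: with 128
birds in 16 families, the sampling standard deviation of $\hat h^2$ is
about 0.16, and that of $\hat m^2$ at a mid-range truth is about 0.2 —
per-replicate estimates scatter widely even though the estimators are
unbiased, which is why the recovery checks above are stated on means over
replicates. (Study-scale analyses of this design report standard errors of
the same order.)

## A worked run

```{r example, eval = FALSE}
b <- make_fixture_bundle("paper_scale", seed = 1)
cfg <- pipeline_config(vcf = b$vcf, otu_counts = b$otu,
                       sample_meta = b$meta, phenotype = b$pheno,
                       tree = b$tree, seed = 1)
res <- run_pipeline(cfg)
cat(report(res$out_dir), sep = "\n")
```

The run writes every intermediate (QC'd table, distance matrices, GRM/MRM,
GWAS results, screen tables) plus a YAML manifest of parameters, stage
seeds and outputs, and the report summarizes α/β diversity per site, the
ANOSIM and Mantel results, $\hat h^2$ with its LRT p, the per-site
$\hat m^2$ table and the screen tallies.

## Limitations

* Model [B] has a single microbial random effect; joint genetic-plus-
  microbial models, GxE, and Bayesian variance components are out of scope.
* The GWAS uses the single-ratio approximation; per-SNP ratio
  re-optimization is not implemented.
* Only ANOSIM is implemented for community differences (the permutational
  MANOVA family is a distinct method, despite the names sometimes being
  conflated).
* Binary-trait heritability is reported on the observed scale; liability-
  scale conversion is a reporting concern left to the caller.
* The simulator is a statistical stand-in for amplicon data; see above.
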
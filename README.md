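# microbiability

Variance partitioning of host-genetic and microbiome effects on
quantitative traits, built around the laying-hen egg-production design:
one flock (128 birds), whole-genome SNP genotypes, OTU tables from six
body sites of the digestive and reproductive tracts (768 samples), and a
single phenotype — EN300, the number of eggs laid by 300 days of age.

The package is for quantitative geneticists and microbiome researchers who
want to ask, in one cohort: how much trait variance do the host genome and
each body site's microbial community explain, and which taxa carry the
signal?

## What it computes

**Relationship matrices.** The genomic relatedness matrix (GRM) from
reference-allele counts,

    h_ij = (1/N) * sum_a (r_ia - 2f_a)(r_ja - 2f_a) / (2 f_a (1 - f_a)),

and the microbial relationship matrix (MRM) per body site — the mean
cross-product of per-OTU standardized abundances,

    r_tij = (1/N_T) * sum_o (a_tio - abar_to)(a_tjo - abar_to) / var_to.

**Variance components.** SNP heritability (h²) and microbiability
(m² = σ²_m / σ²_p) by exact spectral REML for the two single-random-effect
models `y = Xc + g + e`, `g ~ N(0, G σ²_A)` and `y = Xc + m + e`,
`m ~ N(0, M σ²_m)`, with average-information standard errors and a
boundary-mixture (½χ²₀ + ½χ²₁) likelihood-ratio test. Host-genetic
covariates for the m² model come from an EMMAX-style mixed-model GWAS
(5 genotype PCs + 2 PCs of SNPs with p < 1e-6).

**Community statistics.** Rarefaction, Chao1/ACE/Shannon/Simpson/Good's
coverage, Bray-Curtis and (normalized) UniFrac distances, PCoA, ANOSIM and
two-sided Mantel tests with seeded add-one permutation p-values.

**Taxon screens.** Per-taxon heritability with the prevalence
dichotomization rule (<20% excluded; 20–60% presence/absence; ≥60%
quantitative), and the three-way trait-association overlap screen
(extreme-group Wilcoxon with FDR, plus BH-adjusted Pearson and Spearman
correlations — a taxon passes only if all three agree).

**A simulator with known ground truth** (`simulation_truth()`,
`make_fixture_bundle()`): family-structured flocks, site-specific
communities with shared community-state factors, SNP-driven taxa, and a
phenotype whose genetic/microbial/residual variance shares are realized
exactly — so every estimator above is testable end to end without any
external data.

## A worked example

```r
library(microbiability)

b <- make_fixture_bundle("paper_scale", seed = 1)   # 128 birds x 6 sites,
                                                    # 5,000 SNPs, 500 OTUs
cfg <- pipeline_config(vcf = b$vcf, otu_counts = b$otu,
                       sample_meta = b$meta, phenotype = b$pheno,
                       tree = b$tree, seed = 1)
res <- run_pipeline(cfg)
cat(report(res$out_dir), sep = "\n")
```

Excerpts of the report this prints (seed 1):

```
ANOSIM across sites: R = 0.918, p = 0.0001 (10000 permutations).

## Heritability of the trait: h2 = 0.426 (SE 0.216), LRT p = 0.00108

## Microbiability per site

site | m2 | SE | LRT p
---- | -- | -- | -----
crop | 0.000 |   NA | 1
gizzard | 0.083 | 0.130 | 0.193
isthmus | 0.821 | 0.151 | 5.53e-14
small_intestine | 0.000 |   NA | 1
uterus | 0.130 | 0.179 | 0.197
vagina | 0.334 | 0.263 | 0.364
```

Reading it: the six site communities are almost perfectly separable
(ANOSIM R near 1); the trait is moderately heritable (this bundle's
generative h² is 0.282 — note the size of the SE at n = 128, which is why
recovery claims are made on means over replicates, not single runs); and
the site that drives the simulated microbial effect (isthmus, generative
share 0.6) is the only one with a large, strongly significant m², while
decoy sites sit near zero. The screen tallies and per-site Mantel tests
(GRM vs Bray-Curtis, |r| ≤ 0.03 here) are in the full report, and every
intermediate table is written next to the manifest in `res$out_dir`.

A thin command-line wrapper over the same functions is in
`inst/scripts/microbiability-cli.R` (subcommands `simulate`, `run`,
`report`).

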
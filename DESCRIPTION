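Package: microbiability
Title: Variance Partitioning of Host Genetics and Microbiome Effects on
    Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to partition the variance of a quantitative trait (such
    as egg number by 300 days, EN300, in laying hens) into host-genetic and
    microbial components using relationship matrices. Builds genomic
    relatedness matrices (GRM) from reference-allele dosages and microbial
    relationship matrices (MRM) from standardized OTU abundances, estimates
    SNP-based heritability (h2) and microbiability (m2) by spectral
    restricted maximum likelihood with likelihood-ratio tests, runs an
    EMMAX-style linear mixed-model association scan to construct
    host-genetic covariates, and screens taxa for heritability (with
    prevalence-based dichotomization) and for trait association (Wilcoxon
    rank-sum, Pearson and Spearman overlap with Benjamini-Hochberg FDR).
    Includes OTU-table diversity statistics (rarefaction, Chao1, ACE,
    Shannon, Simpson, Good's coverage, Bray-Curtis, UniFrac, PCoA),
    permutation tests (ANOSIM, Mantel), a simulator for genotype,
    microbiome and phenotype data with known ground truth, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
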
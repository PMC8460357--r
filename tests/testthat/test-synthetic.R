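# The simulator: determinism, distributional properties, planted signals.

test_that("genotype simulation is deterministic and respects the dosage coding", {
  g1 <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), seed = 1)
  g2 <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), seed = 1)
  expect_identical(g1$calls, g2$calls)
  expect_true(all(g1$calls %in% 0:2))
  expect_equal(dim(g1), c(4L, 3L))
  expect_error(simulate_genotypes(4, 3, maf_range = c(0.4, 0.1)), "maf_range")
})

test_that("realized allele frequencies are approximately uniform over the MAF range", {
  g <- simulate_genotypes(1000, 5000, maf_range = c(0.05, 0.5), seed = 2)
  f <- allele_freq(g)
  maf <- pmin(f, 1 - f)
  ks <- suppressWarnings(stats::ks.test(maf, "punif", 0.05, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("family structure raises within-family relatedness", {
  g <- simulate_genotypes(64, 2000, seed = 3, n_families = 8)
  grm <- compute_grm(filter_variants(g))$mat
  fam <- rep(1:8, length.out = 64)
  within <- grm[outer(fam, fam, "==") & upper.tri(grm)]
  between <- grm[outer(fam, fam, "!=") & upper.tri(grm)]
  expect_gt(mean(within), mean(between) + 0.3)   # full sibs ~0.5 vs ~0
})

test_that("null communities show no dosage-abundance association; planted taxa do", {
  truth0 <- simulation_truth(5, n_birds = 128, n_snps = 300, n_otus = 80,
                             sites = "crop", true_h2 = 0, true_m2 = c(crop = 0),
                             n_heritable_taxa = 0)
  g <- simulate_genotypes(128, 300, seed = 6, n_families = 16)
  otu0 <- simulate_otu_table(truth0, g)
  rel <- otu0$counts / rowSums(otu0$counts)
  cors <- apply(rel, 2, function(a) cor(a, g$calls[, 1], method = "spearman"))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.05)

  truth1 <- simulation_truth(5, n_birds = 128, n_snps = 300, n_otus = 80,
                             sites = "crop", true_h2 = 0, true_m2 = c(crop = 0),
                             n_heritable_taxa = 1, taxon_h2 = 0.9,
                             snps_per_taxon = 1)
  otu1 <- simulate_otu_table(truth1, g)
  arch <- attr(otu1, "architecture")
  taxon <- arch$heritable_taxa[1]
  snp <- arch$driver_snps[[1]][1]
  sub <- site_subset(otu1, "crop")
  a <- sub$counts[, taxon] / rowSums(sub$counts)
  dos <- g$calls[sub$meta$bird_id, snp]
  ct <- suppressWarnings(cor.test(a, dos, method = "spearman"))
  expect_lt(ct$p.value, 0.01)
})

test_that("distinct site compositions separate almost perfectly under ANOSIM", {
  truth <- simulation_truth(8, n_birds = 20, n_snps = 50, n_otus = 60,
                            sites = c("crop", "isthmus"), true_h2 = 0,
                            true_m2 = c(isthmus = 0), n_heritable_taxa = 0,
                            site_sd = 4)   # near-disjoint dominant taxa
  g <- simulate_genotypes(20, 50, seed = 8)
  otu <- simulate_otu_table(truth, g)
  a <- anosim(bray_curtis(otu), otu$meta$site, n_perm = 199, seed = 1)
  expect_gt(a$statistic, 0.95)
  expect_lt(a$p_value, 0.05)
})

test_that("phenotype variance shares are realized exactly and EN300 scaling works", {
  truth <- simulation_truth(9, n_birds = 64, n_snps = 200, n_otus = 50,
                            sites = "isthmus", true_h2 = 0.3,
                            true_m2 = c(isthmus = 0.4), n_heritable_taxa = 0)
  g <- simulate_genotypes(64, 200, seed = 9, n_families = 8)
  otu <- simulate_otu_table(truth, g)
  ph <- simulate_phenotype(truth, g, otu, "isthmus")
  comp <- attr(ph, "components")
  expect_equal(comp$realized_h2, 0.3, tolerance = 1e-10)
  expect_equal(comp$realized_m2, 0.4, tolerance = 1e-10)
  expect_equal(var(ph$value) * 63 / 64, 1, tolerance = 1e-10)

  expect_error(simulate_phenotype(
    simulation_truth(9, n_birds = 64, true_h2 = 0.6, true_m2 = c(isthmus = 0.6)),
    g, otu, "isthmus"), "exceeds 1")
})

test_that("EN300 emulation lands on the reported scale", {
  truth <- simulation_truth(10, n_birds = 128, n_snps = 300, n_otus = 60,
                            sites = "isthmus", true_h2 = 0.282,
                            true_m2 = c(isthmus = 0.6),
                            emulate_en300 = TRUE)
  g <- simulate_genotypes(128, 300, seed = 10, n_families = 16)
  otu <- simulate_otu_table(truth, g)
  ph <- simulate_phenotype(truth, g, otu, "isthmus")
  expect_gt(mean(ph$value), 70)
  expect_lt(mean(ph$value), 81)
  expect_true(all(ph$value >= 24 & ph$value <= 129))
})

test_that("coalescent trees over OTUs are deterministic and well formed", {
  t2 <- simulate_tree(c("A", "B"), seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(nrow(t2$edge), 2L)
  expect_identical(ape::write.tree(simulate_tree(letters, 3)),
                   ape::write.tree(simulate_tree(letters, 3)))
  t100 <- simulate_tree(sprintf("OTU%03d", 1:100), seed = 4)
  expect_true(is.finite(sum(t100$edge.length)) && sum(t100$edge.length) > 0)
  expect_error(simulate_tree("A"), "at least 2")
})

test_that("fixture bundles are byte-identical given (profile, seed)", {
  d1 <- tempfile("b1_"); d2 <- tempfile("b2_")
  make_fixture_bundle("tiny", 5, d1)
  make_fixture_bundle("tiny", 5, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(make_fixture_bundle("huge", 1), "unknown profile")
})

test_that("the study-scale bundle has one sample per bird and site", {
  b <- make_fixture_bundle("paper_scale", 1)
  otu <- read_otu_table(b$otu, b$meta)
  expect_equal(nrow(otu$counts), 768L)
  expect_equal(length(unique(otu$meta$site)), 6L)
  expect_equal(length(unique(otu$meta$bird_id)), 128L)
})
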
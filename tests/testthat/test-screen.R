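# Prevalence-based mode assignment, extreme groups, and the two taxon screens.

test_that("analysis mode is piecewise constant with breakpoints exactly at 0.20 and 0.60", {
  expect_equal(assign_mode(0.15), "excluded")
  expect_equal(assign_mode(0.25), "binary")
  expect_equal(assign_mode(0.60), "quantitative")
  grid <- seq(0, 1, by = 0.001)
  modes <- assign_mode(grid)
  expect_equal(unique(modes[grid < 0.20]), "excluded")
  expect_equal(unique(modes[grid >= 0.20 & grid < 0.60]), "binary")
  expect_equal(unique(modes[grid >= 0.60]), "quantitative")
  # breakpoints and nothing else
  flips <- grid[which(modes[-1] != modes[-length(modes)]) + 1]
  expect_equal(flips, c(0.20, 0.60))
  expect_error(assign_mode(1.2), "\\[0, 1\\]")
})

test_that("extreme groups take floor(fraction*n) from each tail, deterministically under ties", {
  ph <- data.frame(bird_id = sprintf("b%02d", 1:10), value = 1:10)
  gr <- extreme_groups(ph, 0.2)
  expect_equal(gr$low, c("b01", "b02"))
  expect_equal(gr$high, c("b10", "b09"))

  ph128 <- data.frame(bird_id = sprintf("b%03d", 1:128),
                      value = withr::with_seed(50, rnorm(128)))
  gr128 <- extreme_groups(ph128, 0.2)
  expect_equal(gr128$size, 25L)
  expect_equal(length(intersect(gr128$low, gr128$high)), 0L)

  tie <- data.frame(bird_id = sprintf("b%02d", 1:10),
                    value = c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10))
  g1 <- extreme_groups(tie, 0.3); g2 <- extreme_groups(tie[sample(10), ], 0.3)
  expect_equal(sort(g1$low), sort(g2$low))     # stable under row order
  expect_equal(g1$low, c("b01", "b02", "b03")) # ID-ordered among tied values
  expect_error(extreme_groups(ph, 0.5), "< 0.5")
  expect_error(extreme_groups(ph[1:5, ], 0.2), "at least 10")
})

test_that("the heritability screen excludes rare taxa and recovers a strongly heritable one", {
  truth <- simulation_truth(51, n_birds = 96, n_snps = 400, n_otus = 40,
                            sites = "uterus", true_h2 = 0,
                            true_m2 = c(uterus = 0), n_heritable_taxa = 3,
                            taxon_h2 = 0.85)
  g <- simulate_genotypes(96, 400, seed = 51, n_families = 12)
  otu <- simulate_otu_table(truth, g)
  grm <- compute_grm(filter_variants(g))
  scr <- taxon_heritability_screen(otu, "uterus", grm, n_pcs = 3)
  expect_equal(nrow(scr), 40L)
  expect_true(all(scr$mode[scr$prevalence < 0.2] == "excluded"))
  expect_true(all(is.na(scr$h2[scr$mode == "excluded"])))
  planted <- attr(otu, "architecture")$heritable_taxa
  tested <- scr[scr$taxon %in% planted & scr$mode != "excluded", ]
  expect_gt(sum(tested$heritable), 0)
})

test_that("cumulative heritable abundance sums mean relative abundances", {
  cnt <- rbind(c(10, 30, 60), c(20, 20, 60), c(0, 40, 60))
  colnames(cnt) <- paste0("OTU", 1:3)
  otu <- toy_otu(cnt, sites = rep("crop", 3))
  scr <- data.frame(taxon = colnames(cnt), heritable = c(TRUE, TRUE, FALSE))
  expected <- mean(cnt[, 1] / 100) + mean(cnt[, 2] / 100)
  expect_equal(cumulative_heritable_abundance(scr, otu, "crop"), expected)
  scr0 <- data.frame(taxon = colnames(cnt), heritable = FALSE)
  expect_equal(cumulative_heritable_abundance(scr0, otu, "crop"), 0)
  scr1 <- data.frame(taxon = colnames(cnt), heritable = TRUE)
  expect_equal(cumulative_heritable_abundance(scr1, otu, "crop"), 1)
})

test_that("the overlap screen passes a planted taxon and rejects a rank-only association", {
  truth <- simulation_truth(52, n_birds = 128, n_snps = 100, n_otus = 60,
                            sites = "isthmus", true_h2 = 0,
                            true_m2 = c(isthmus = 0.6), n_heritable_taxa = 0,
                            n_assoc_taxa = 2)
  g <- simulate_genotypes(128, 100, seed = 52, n_families = 16)
  otu <- simulate_otu_table(truth, g)
  ph <- simulate_phenotype(truth, g, otu, "isthmus")
  scr <- en300_microbe_screen(otu, "isthmus", ph)
  planted <- attr(otu, "architecture")$assoc_taxa
  hits <- scr[scr$taxon %in% planted, ]
  expect_gt(sum(hits$pass), 0)
  expect_equal(hits$sign[hits$pass],
               attr(otu, "architecture")$assoc_sign[match(hits$taxon[hits$pass],
                                                          planted)])

  # monotone but Pearson-weak association: spearman perfect, pearson n.s.
  n <- 20
  y <- 1:20
  abun <- c(seq_len(19) * 1e-6, 1)          # one dominant bird
  cnt <- cbind(t1 = round(abun * 1e6), filler = rep(1000L, n))
  otu2 <- toy_otu(cnt)
  ph2 <- data.frame(bird_id = paste0("B", 1:n), value = y)
  scr2 <- en300_microbe_screen(otu2, "crop", ph2)
  row <- scr2[scr2$taxon == "t1", ]
  expect_lt(row$spearman_adj_p, 0.05)
  expect_gt(row$pearson_adj_p, 0.05)
  expect_false(row$pass)
})

test_that("extreme-abundance grouping contrasts phenotypes and rejects constant taxa", {
  truth <- simulation_truth(53, n_birds = 128, n_snps = 100, n_otus = 60,
                            sites = "isthmus", true_h2 = 0,
                            true_m2 = c(isthmus = 0.6), n_heritable_taxa = 0,
                            n_assoc_taxa = 1)
  g <- simulate_genotypes(128, 100, seed = 53, n_families = 16)
  otu <- simulate_otu_table(truth, g)
  ph <- simulate_phenotype(truth, g, otu, "isthmus")
  taxon <- attr(otu, "architecture")$assoc_taxa[1]
  res <- extreme_abundance_phenotype_compare(otu, "isthmus", taxon, ph,
                                             n_perm = 999, seed = 1)
  expect_gt(res$mean_high, res$mean_low)    # planted positive direction
  expect_lt(res$p_value, 0.05)

  flat <- toy_otu(cbind(t1 = rep(5L, 12), t2 = rep(7L, 12)))
  ph_flat <- data.frame(bird_id = paste0("B", 1:12), value = rnorm(12))
  expect_error(extreme_abundance_phenotype_compare(flat, "crop", "t1", ph_flat),
               "constant")
})
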
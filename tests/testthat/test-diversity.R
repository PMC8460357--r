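# Rarefaction, alpha diversity, beta diversity, PCoA.

test_that("prevalence filter is inclusive at the threshold and unions across sites", {
  cnt <- cbind(rare = c(5, rep(0, 9)),            # 1/10 samples
               boundary = c(3, 2, rep(0, 8)),     # exactly 2/10
               common = rep(1, 10))
  otu <- toy_otu(cnt)
  out <- prevalence_filter(otu, 0.2)
  expect_setequal(colnames(out$counts), c("boundary", "common"))
  out_all <- prevalence_filter(otu, 1.0)
  expect_equal(colnames(out_all$counts), "common")

  # present in >=20% of one site only: kept by the per-site union
  cnt2 <- cbind(site_a_only = c(2, 2, 0, 0), common = c(1, 1, 1, 1))
  otu2 <- toy_otu(cnt2, sites = c("a", "a", "b", "b"))
  expect_setequal(colnames(prevalence_filter(otu2, 0.5)$counts),
                  c("site_a_only", "common"))
})

test_that("rarefaction conserves depth and matches the hypergeometric mean", {
  otu <- toy_otu(rbind(c(10, 0), c(8, 12), c(30, 5)))
  r <- rarefy(otu, depth = 5, seed = 1)
  expect_true(all(rowSums(r$counts) == 5))
  expect_equal(unname(r$counts[1, ]), c(5, 0))
  expect_error(rarefy(otu, depth = 12), "S1")
  expect_identical(rarefy(otu, 5, seed = 2)$counts, rarefy(otu, 5, seed = 2)$counts)

  # mean count of the first OTU when rarefying (6,4) to 5 is 5*6/10 = 3
  one <- toy_otu(rbind(c(6, 4)))
  draws <- vapply(1:4000, function(s) rarefy(one, 5, seed = s)$counts[1, 1], 0)
  expect_equal(mean(draws), 3.0, tolerance = 0.03)
})

test_that("alpha-diversity indices match their closed forms", {
  a <- alpha_diversity(toy_otu(rbind(c(25, 25, 25, 25))))
  expect_equal(a$observed_otus, 4L)
  expect_equal(a$shannon, 2.0)
  expect_equal(a$simpson, 0.75)

  # S_obs = 10, F1 = 4, F2 = 2 -> chao1 = 10 + 4*3/(2*3) = 12
  cnt <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  a2 <- alpha_diversity(toy_otu(rbind(cnt)))
  expect_equal(a2$chao1, 12.0)
  expect_equal(a2$goods_coverage, 1 - 4 / sum(cnt))

  # no singletons: chao1 = S_obs, Good's coverage = 1
  a3 <- alpha_diversity(toy_otu(rbind(c(5, 5, 2))))
  expect_equal(a3$chao1, 3)
  expect_equal(a3$goods_coverage, 1.0)

  expect_error(alpha_diversity(toy_otu(rbind(c(1, 1), c(0, 0)))), "S2")
})

test_that("Bray-Curtis matches its definition and bounds", {
  otu <- toy_otu(rbind(c(1, 2), c(3, 0), c(1, 2)))
  d <- as.matrix(bray_curtis(otu))
  expect_equal(d[1, 2], 4 / 6, tolerance = 1e-12)
  expect_equal(d[1, 3], 0)
  disj <- toy_otu(rbind(c(5, 0), c(0, 7)))
  expect_equal(as.matrix(bray_curtis(disj))[1, 2], 1)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("UniFrac agrees with a brute-force edge tally and hand values", {
  tree <- read_tree(write_lines_tmp("((A:1,B:1):1,C:2);", ".nwk"))
  cnt <- rbind(s1 = c(A = 1, B = 0, C = 0),
               s2 = c(A = 0, B = 0, C = 1),
               s3 = c(A = 1, B = 1, C = 0),
               s4 = c(A = 1, B = 0, C = 1))
  otu <- toy_otu(cnt)
  du <- as.matrix(unifrac(otu, tree, weighted = FALSE))
  dw <- as.matrix(unifrac(otu, tree, weighted = TRUE))
  # disjoint single-OTU communities share no branch
  expect_equal(du["s1", "s2"], 1)
  expect_equal(dw["s1", "s2"], 1)
  # {A,B} vs {A,C}: unique = B(1) + C(2), either = A(1)+B(1)+C(2)+internal(1)
  expect_equal(du["s3", "s4"], 3 / 5, tolerance = 1e-12)
  expect_equal(dw["s3", "s4"], 2 / 4, tolerance = 1e-12)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(du[i, j], brute_unifrac_pair(tree, cnt[i, ], cnt[j, ], FALSE),
                 tolerance = 1e-12)
    expect_equal(dw[i, j], brute_unifrac_pair(tree, cnt[i, ], cnt[j, ], TRUE),
                 tolerance = 1e-12)
  }
  expect_error(unifrac(toy_otu(rbind(c(X1 = 1, X2 = 1))), tree), "missing from tree")
})

test_that("beta metrics are invariant to OTU order; unweighted also to depth scaling", {
  truth <- simulation_truth(3, n_birds = 10, n_snps = 20, n_otus = 15,
                            sites = "crop", true_h2 = 0, true_m2 = c(crop = 0),
                            n_heritable_taxa = 0)
  g <- simulate_genotypes(10, 20, seed = 3)
  otu <- simulate_otu_table(truth, g)
  tree <- simulate_tree(colnames(otu$counts), 4)
  perm <- withr::with_seed(5, sample(ncol(otu$counts)))
  otu_p <- mb_otu_table(otu$counts[, perm], otu$meta)
  expect_equal(as.matrix(bray_curtis(otu)), as.matrix(bray_curtis(otu_p)))
  expect_equal(as.matrix(unifrac(otu, tree)), as.matrix(unifrac(otu_p, tree)))

  scaled <- otu$counts; scaled[3, ] <- scaled[3, ] * 7L
  otu_s <- mb_otu_table(scaled, otu$meta)
  expect_equal(as.matrix(unifrac(otu, tree)), as.matrix(unifrac(otu_s, tree)),
               tolerance = 1e-12)
})

test_that("PCoA recovers Euclidean configurations and flags degenerate input", {
  pts1 <- cbind(c(0, 1, 3), 0)                    # collinear
  p1 <- pcoa(euclid_dist(pts1), k = 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-9)

  pts2 <- withr::with_seed(6, matrix(rnorm(20), 10, 2))
  p2 <- pcoa(euclid_dist(pts2), k = 2)
  expect_equal(as.matrix(dist(p2$coordinates)), euclid_dist(pts2),
               tolerance = 1e-9, ignore_attr = TRUE)
  # Gram-spectrum oracle: eigenvalues of the centered configuration
  ctr <- scale(pts2, scale = FALSE)
  expect_equal(sort(p2$eigenvalues, decreasing = TRUE)[1:2],
               sort(eigen(tcrossprod(ctr))$values, decreasing = TRUE)[1:2],
               tolerance = 1e-9)

  expect_error(pcoa(matrix(0, 3, 3), k = 1), "degenerate")
  expect_error(pcoa(euclid_dist(pts2), k = 0), "k must be")
})
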
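# Spectral REML, heritability/microbiability wrappers, LMM association scan.

sim_h2_instance <- function(n, m, h2, seed, n_families = NULL) {
  g <- simulate_genotypes(n, m, seed = seed, n_families = n_families)
  f <- allele_freq(g)
  g <- genotype_matrix(g$calls[, f > 0 & f < 1, drop = FALSE],
                       g$map[f > 0 & f < 1, ], imputed = TRUE)
  grm <- compute_grm(g)
  y <- withr::with_seed(seed + 1000, {
    u <- as.numeric(scale(g$calls, scale = FALSE) %*% rnorm(ncol(g$calls)))
    u <- if (h2 > 0) (u - mean(u)) / sqrt(mean((u - mean(u))^2)) * sqrt(h2) else u * 0
    e <- rnorm(n)
    e <- (e - mean(e)) / sqrt(mean((e - mean(e))^2)) * sqrt(1 - h2)
    u + e
  })
  list(g = g, grm = grm, y = y)
}

test_that("the spectral restricted likelihood equals the dense-matrix form", {
  inst <- sim_h2_instance(25, 40, 0.5, seed = 30)
  X <- cbind(1, withr::with_seed(31, rnorm(25)))
  e <- eigen(inst$grm$mat, symmetric = TRUE)
  yt <- crossprod(e$vectors, inst$y)[, 1]
  Xt <- crossprod(e$vectors, X)
  for (lam in c(0.01, 0.5, 2, 40)) {
    expect_equal(microbiability:::reml_profile_ll(lam, pmax(e$values, 0), yt, Xt),
                 dense_reml_ll(lam, inst$y, inst$grm$mat, X), tolerance = 1e-8)
  }
})

test_that("the REML optimum dominates both boundary candidates", {
  for (seed in c(32, 33, 34)) {
    inst <- sim_h2_instance(40, 60, 0.4, seed = seed)
    fit <- reml_single_component(inst$y, inst$grm)
    ll_lo <- dense_reml_ll(1e-9, inst$y, inst$grm$mat, matrix(1, 40, 1))
    ll_hi <- dense_reml_ll(1e6, inst$y, inst$grm$mat, matrix(1, 40, 1))
    expect_gte(fit$loglik_full + 1e-6, ll_lo)
    expect_gte(fit$loglik_full + 1e-6, ll_hi)
  }
})

test_that("an identity-like relationship matrix is flagged unidentifiable", {
  y <- withr::with_seed(35, rnorm(30))
  expect_error(reml_single_component(y, diag(30)), "unidentifiable")
})

test_that("h2 estimation is location-invariant and near zero for permuted traits", {
  inst <- sim_h2_instance(100, 500, 0.5, seed = 36, n_families = 12)
  ph <- data.frame(bird_id = rownames(inst$g$calls), value = inst$y)
  fit1 <- estimate_h2(ph, inst$grm, n_pcs = 2)
  ph2 <- ph; ph2$value <- ph2$value + 100
  fit2 <- estimate_h2(ph2, inst$grm, n_pcs = 2)
  expect_equal(fit1$ratio, fit2$ratio, tolerance = 1e-6)
  expect_gt(fit1$ratio, 0.1)

  ph3 <- ph; ph3$value <- withr::with_seed(37, sample(ph$value))
  fit3 <- estimate_h2(ph3, inst$grm, n_pcs = 2)
  expect_lt(fit3$ratio, 0.25)
})

test_that("the LRT p-value respects the boundary mixture form", {
  inst <- sim_h2_instance(60, 100, 0.6, seed = 38, n_families = 10)
  fit <- reml_single_component(inst$y, inst$grm)
  expect_equal(fit$lrt_p, 0.5 * pchisq(fit$lrt, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gte(fit$lrt, 0)
  null_inst <- sim_h2_instance(60, 100, 0, seed = 39, n_families = 10)
  nf <- reml_single_component(null_inst$y, null_inst$grm)
  expect_equal(nf$lrt_p, if (nf$lrt <= 0) 1 else
    0.5 * pchisq(nf$lrt, 1, lower.tail = FALSE))
})

test_that("a planted causal SNP reaches genome-wide significance; nulls stay calibrated", {
  n <- 300
  g <- simulate_genotypes(n, 2000, seed = 40)
  f <- allele_freq(g)
  g <- genotype_matrix(g$calls[, f > 0.05 & f < 0.95, drop = FALSE],
                       g$map[f > 0.05 & f < 0.95, ], imputed = TRUE)
  grm <- compute_grm(g)
  causal <- 7L
  y <- withr::with_seed(41, {
    dose <- g$calls[, causal]
    b <- sqrt(0.2 / var(dose))
    dose * b + rnorm(n, sd = sqrt(0.8))
  })
  ph <- data.frame(bird_id = rownames(g$calls), value = y)
  scan <- lmm_gwas_scan(ph, g, grm)
  expect_lt(scan$results$p[causal], 1e-6)
  expect_equal(which.min(scan$results$p), causal)

  y0 <- withr::with_seed(42, rnorm(n))
  scan0 <- lmm_gwas_scan(data.frame(bird_id = rownames(g$calls), value = y0),
                         g, grm)
  expect_gt(scan0$lambda_gc, 0.9)
  expect_lt(scan0$lambda_gc, 1.1)
  ks <- suppressWarnings(ks.test(scan0$results$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("monomorphic or collinear SNPs are skipped with a flag", {
  g <- simulate_genotypes(50, 30, seed = 43)
  g$calls[, 3] <- 2L                  # monomorphic
  f <- allele_freq(g)
  keep <- (f > 0 & f < 1) | seq_along(f) == 3
  g <- genotype_matrix(g$calls[, keep, drop = FALSE], g$map[keep, ],
                       imputed = TRUE)
  grm_src <- genotype_matrix(g$calls[, colnames(g$calls) != "snp00003"],
                             g$map[g$map$snp_id != "snp00003", ], imputed = TRUE)
  grm <- compute_grm(grm_src)
  ph <- data.frame(bird_id = rownames(g$calls),
                   value = withr::with_seed(44, rnorm(50)))
  scan <- lmm_gwas_scan(ph, g, grm)
  expect_true(scan$results$skipped[scan$results$snp_id == "snp00003"])
  expect_true(is.na(scan$results$p[scan$results$snp_id == "snp00003"]))
})

test_that("significant-SNP PCs behave at zero, one and many hits", {
  g <- simulate_genotypes(40, 20, seed = 45)
  fake <- list(results = data.frame(snp_id = g$map$snp_id, chrom = g$map$chrom,
                                    pos = g$map$pos, beta = 0, se = 1,
                                    p = rep(0.5, 20), skipped = FALSE))
  expect_warning(pcs0 <- significant_snp_pcs(fake, g), "empty covariate")
  expect_equal(ncol(pcs0), 0L)

  fake$results$p[4] <- 1e-9
  pcs1 <- significant_snp_pcs(fake, g)
  dose <- scale(g$calls[, 4])
  expect_equal(abs(cor(pcs1[, 1], dose[, 1])), 1, tolerance = 1e-8)

  fake$results$p[c(2, 9, 15)] <- 1e-8
  pcs2 <- significant_snp_pcs(fake, g, k = 2)
  expect_equal(ncol(pcs2), 2L)
  expect_lt(abs(crossprod(pcs2)[1, 2]), 1e-8)
})

test_that("m2 falls to zero when the microbiome is shuffled across birds", {
  truth <- simulation_truth(46, n_birds = 100, n_snps = 200, n_otus = 150,
                            sites = "isthmus", true_h2 = 0,
                            true_m2 = c(isthmus = 0.8), n_heritable_taxa = 0)
  g <- simulate_genotypes(100, 200, seed = 46, n_families = 12)
  otu <- simulate_otu_table(truth, g)
  ph <- simulate_phenotype(truth, g, otu, "isthmus")
  mrm <- suppressWarnings(compute_mrm(otu, "isthmus", abundance_mode = "relative"))
  fit <- estimate_m2(ph, mrm)
  expect_gt(fit$ratio, 0.5)

  perm <- withr::with_seed(47, sample(100))
  shuf <- mrm
  shuf$mat <- mrm$mat[perm, perm]        # break the bird alignment
  dimnames(shuf$mat) <- dimnames(mrm$mat)
  fit0 <- estimate_m2(ph, shuf)
  expect_lt(fit0$ratio, 0.25)
})
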
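#' Ground-truth parameters for a simulated host-genetics x microbiome study
#'
#' Describes the generative model used by [simulate_genotypes()],
#' [simulate_otu_table()] and [simulate_phenotype()]: a flock of birds with
#' full-sib family structure, six body-site microbial communities with
#' site-specific composition and a low-rank "community state" covariance
#' across taxa, a minority of taxa whose abundance is driven by host SNPs,
#' and a quantitative trait (EN300-like) whose variance is split exactly into
#' genetic, microbial and residual shares.
#'
#' Default sizes mirror the laying-hen study design this package targets:
#' 128 birds x 6 sites (768 samples), with a desk-scale 5,000 SNPs and 500
#' OTUs standing in for the full resequencing/16S panels. The default trait
#' shares are h2 = 0.282 (the study-scale SNP heritability of EN300) and a
#' microbial share of 0.6 acting through the isthmus community, the site the
#' egg-production analysis singles out.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param n_birds,n_snps,n_otus simulated dimensions.
#' @param sites character vector of body-site labels.
#' @param true_h2 genetic share of trait variance, in `[0, 1]`.
#' @param true_m2 named numeric vector of microbial trait-variance shares per
#'   site (sites not named get 0). `true_h2 + max(true_m2)` must be <= 1.
#' @param family_size full-sib family size (`1` = unrelated birds).
#' @param maf_range SNP allele frequencies are drawn uniformly from this range.
#' @param n_heritable_taxa number of taxa whose latent abundance carries a
#'   host-genetic component.
#' @param taxon_h2 genetic share of latent log-abundance for heritable taxa.
#' @param snps_per_taxon number of driver SNPs per heritable taxon
#'   (`NULL`, the default, means every SNP contributes, i.e. polygenic
#'   control; a finite subset gives an oligogenic architecture whose
#'   GRM-based heritability is attenuated by imperfect tagging).
#' @param n_assoc_taxa if > 0, the microbial trait effect is concentrated on
#'   this many "phenotype-associated" taxa (alternating sign) instead of
#'   acting densely through all taxa. Associated taxa form a correlated
#'   guild: half of each one's bird-level latent variance is a shared
#'   community factor (entered with the taxon's sign), the way co-occurring
#'   trait-associated taxa behave in real communities.
#' @param site_sd standard deviation of per-site log-mean abundances (site
#'   separation; larger values give more distinct communities and a more
#'   skewed rank-abundance curve). The default keeps most taxa common enough
#'   that multinomial sampling noise stays a minor share of abundance
#'   variance at the default depth, so the simulated variance shares remain
#'   interpretable by the downstream relationship-matrix models.
#' @param n_factors,factor_share rank and variance share of the shared
#'   community-state component of bird-level abundance noise.
#' @param bird_sd total bird-level standard deviation of latent
#'   log-abundance per taxon.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters.
#'   The defaults (about 50k reads per sample with modest spread) keep
#'   multinomial sampling noise a minor share of per-taxon abundance
#'   variance even after rarefaction to the minimum depth, so the
#'   relationship-matrix models see the biological signal the truth
#'   parameters define.
#' @param emulate_en300 if `TRUE`, [simulate_phenotype()] maps the trait to
#'   the EN300 scale (mean 75.32, sd 17.5, clipped to `[24, 129]`).
#'
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(seed,
                             n_birds = 128,
                             n_snps = 5000,
                             n_otus = 500,
                             sites = c("crop", "gizzard", "small_intestine",
                                       "vagina", "uterus", "isthmus"),
                             true_h2 = 0.282,
                             true_m2 = c(isthmus = 0.6),
                             family_size = 8,
                             maf_range = c(0.05, 0.5),
                             n_heritable_taxa = 25,
                             taxon_h2 = 0.8,
                             snps_per_taxon = NULL,
                             n_assoc_taxa = 0,
                             site_sd = 1,
                             bird_sd = 1,
                             n_factors = 3,
                             factor_share = 0.5,
                             depth_meanlog = log(50000),
                             depth_sdlog = 0.25,
                             emulate_en300 = FALSE) {
  assert_fraction(true_h2, "true_h2")
  if (is.null(names(true_m2)) && length(true_m2) == length(sites))
    names(true_m2) <- sites
  m2 <- stats::setNames(rep(0, length(sites)), sites)
  m2[intersect(names(true_m2), sites)] <- true_m2[intersect(names(true_m2), sites)]
  if (true_h2 + max(m2) > 1)
    stop_mb("true_h2 + true_m2 share exceeds 1 (%.3f + %.3f)", true_h2, max(m2))
  structure(list(seed = as.integer(seed), n_birds = n_birds, n_snps = n_snps,
                 n_otus = n_otus, sites = sites, true_h2 = true_h2,
                 true_m2 = m2, family_size = family_size,
                 maf_range = maf_range,
                 n_heritable_taxa = n_heritable_taxa, taxon_h2 = taxon_h2,
                 snps_per_taxon = snps_per_taxon, n_assoc_taxa = n_assoc_taxa,
                 site_sd = site_sd, bird_sd = bird_sd,
                 n_factors = n_factors,
                 factor_share = factor_share, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, emulate_en300 = emulate_en300),
            class = "simulation_truth")
}

#' Simulate SNP genotypes for a flock
#'
#' Allele frequencies are drawn uniformly from `maf_range`. With
#' `n_families = NULL` every bird is unrelated and genotypes are binomial(2,
#' f) draws; otherwise birds are grouped into full-sib families and each
#' offspring inherits one allele per SNP from each of two unobserved parents
#' (gene dropping), giving the within-flock relatedness a single-hatch layer
#' cohort actually has. SNPs are unlinked and laid out on 10 chromosomes at
#' 2-kb spacing.
#'
#' @param n_birds,n_snps dimensions (`n_birds >= 2`, `n_snps >= 1`).
#' @param maf_range length-2 numeric inside `(0, 0.5]`.
#' @param seed RNG seed (deterministic output).
#' @param n_families number of full-sib families, or `NULL` for unrelated.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_birds, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1, n_families = NULL) {
  if (n_birds < 2 || n_snps < 1) stop_mb("need n_birds >= 2 and n_snps >= 1")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_mb("maf_range must be increasing and inside (0, 0.5]")
  calls <- withr::with_seed(seed, {
    f <- stats::runif(n_snps, maf_range[1], maf_range[2])
    if (is.null(n_families) || n_families >= n_birds) {
      matrix(stats::rbinom(n_birds * n_snps, 2, rep(f, each = n_birds)),
             nrow = n_birds)
    } else {
      fam <- rep(seq_len(n_families), length.out = n_birds)
      out <- matrix(0L, n_birds, n_snps)
      for (k in seq_len(n_families)) {
        p1 <- stats::rbinom(n_snps, 2, f)
        p2 <- stats::rbinom(n_snps, 2, f)
        for (i in which(fam == k))
          out[i, ] <- stats::rbinom(n_snps, 1, p1 / 2) +
                      stats::rbinom(n_snps, 1, p2 / 2)
      }
      out
    }
  })
  rownames(calls) <- sprintf("B%03d", seq_len(n_birds))
  n_chr <- min(10L, n_snps)
  chrom <- sort(rep_len(seq_len(n_chr), n_snps))
  pos <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along) * 2000L
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
                    chrom = as.character(chrom), pos = pos,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}

# deterministic choice of heritable / phenotype-associated taxa and their
# SNP drivers; shared by simulate_otu_table and the truth manifest
taxon_architecture <- function(truth, g) {
  withr::with_seed(sub_seed(truth$seed, "architecture"), {
    n_her <- min(truth$n_heritable_taxa, truth$n_otus)
    her <- sort(sample.int(truth$n_otus, n_her))
    n_drv <- if (is.null(truth$snps_per_taxon)) ncol(g$calls)
             else min(truth$snps_per_taxon, ncol(g$calls))
    drivers <- lapply(her, function(o)
      if (n_drv == ncol(g$calls)) seq_len(ncol(g$calls))
      else sort(sample.int(ncol(g$calls), n_drv)))
    effects <- lapply(drivers, function(d) stats::rnorm(length(d)))
    n_assoc <- min(truth$n_assoc_taxa, truth$n_otus)
    assoc <- if (n_assoc > 0) sort(sample.int(truth$n_otus, n_assoc)) else integer(0)
    list(heritable = her, drivers = drivers, effects = effects,
         assoc = assoc,
         assoc_sign = if (n_assoc > 0) rep_len(c(1, -1), n_assoc) else numeric(0))
  })
}

#' Simulate OTU count tables for every body site
#'
#' Per bird-site sample, latent log-abundances are `site mean + host-genetic
#' effect (heritable taxa only) + bird-level noise`, where the noise has a
#' low-rank shared "community state" component across taxa plus an
#' idiosyncratic part. Counts are multinomial draws at a log-normal
#' per-sample depth. The log-normal/multinomial family is a modeling
#' stand-in for real 16S abundance distributions and is flagged as such in
#' the truth manifest.
#'
#' @param truth a [simulation_truth()].
#' @param g the [genotype_matrix()] simulated from the same truth.
#' @return An [mb_otu_table()] with `truth` architecture stored in attribute
#'   `"architecture"` (heritable taxa, driver SNPs, associated taxa).
#' @export
simulate_otu_table <- function(truth, g) {
  n <- nrow(g$calls)
  if (n != truth$n_birds)
    stop_mb("genotype matrix has %d birds but truth says %d", n, truth$n_birds)
  arch <- taxon_architecture(truth, g)
  otu_ids <- sprintf("OTU%04d", seq_len(truth$n_otus))
  birds <- rownames(g$calls)

  # genetic component of latent log-abundance, one column per heritable taxon
  gen <- matrix(0, n, truth$n_otus)
  for (i in seq_along(arch$heritable)) {
    w <- g$calls[, arch$drivers[[i]], drop = FALSE]
    gv <- as.numeric(scale(w, scale = FALSE) %*% arch$effects[[i]])
    gen[, arch$heritable[i]] <- scale_to_share(gv, truth$taxon_h2)
  }
  noise_share <- rep(1, truth$n_otus)
  noise_share[arch$heritable] <- 1 - truth$taxon_h2

  counts_all <- NULL
  meta_all <- NULL
  for (s in truth$sites) {
    seed_s <- sub_seed(truth$seed, paste0("site_", s))
    block <- withr::with_seed(seed_s, {
      mu <- stats::rnorm(truth$n_otus, 0, truth$site_sd)
      L <- matrix(stats::rnorm(truth$n_otus * truth$n_factors,
                               0, sqrt(1 / truth$n_factors)),
                  truth$n_otus, truth$n_factors)
      eta <- matrix(stats::rnorm(n * truth$n_factors), n, truth$n_factors)
      eps <- matrix(stats::rnorm(n * truth$n_otus), n, truth$n_otus)
      noise <- sqrt(truth$factor_share) * eta %*% t(L) +
               sqrt(1 - truth$factor_share) * eps
      if (length(arch$assoc)) {
        guild <- stats::rnorm(n)
        for (i in seq_along(arch$assoc)) {
          o <- arch$assoc[i]
          noise[, o] <- sqrt(0.5) * arch$assoc_sign[i] * guild +
                        sqrt(0.5) * noise[, o]
        }
      }
      x <- sweep(truth$bird_sd * (noise %*% diag(sqrt(noise_share)) + gen),
                 2, mu, "+")
      p <- exp(x - apply(x, 1, max))
      p <- p / rowSums(p)
      depth <- pmax(200L, round(stats::rlnorm(n, truth$depth_meanlog,
                                              truth$depth_sdlog)))
      cnt <- t(vapply(seq_len(n),
                      function(b) stats::rmultinom(1, depth[b], p[b, ])[, 1],
                      integer(truth$n_otus)))
      cnt
    })
    rownames(block) <- paste0(birds, "_", s)
    colnames(block) <- otu_ids
    counts_all <- rbind(counts_all, block)
    meta_all <- rbind(meta_all,
                      data.frame(sample_id = rownames(block), bird_id = birds,
                                 site = s, stringsAsFactors = FALSE))
  }
  out <- mb_otu_table(counts_all, meta_all)
  attr(out, "architecture") <- list(
    heritable_taxa = otu_ids[arch$heritable],
    driver_snps = stats::setNames(lapply(arch$drivers, function(d) g$map$snp_id[d]),
                                  otu_ids[arch$heritable]),
    assoc_taxa = otu_ids[arch$assoc],
    assoc_sign = arch$assoc_sign)
  out
}

#' Simulate a quantitative trait with exact variance shares
#'
#' The trait is `y = u + v + e`: a polygenic host-genetic value `u` built
#' from centered dosages of all SNPs, a microbial value `v` acting through
#' per-OTU standardized relative abundances at the driving `site` (matching
#' the MRM standardization, so the microbial share is well-defined under the
#' one-random-effect microbiability model), and iid residual `e`. The three
#' components are orthogonalized and rescaled so the realized population
#' variance shares equal `true_h2`, `true_m2[site]` and the remainder
#' exactly. If the truth's `n_assoc_taxa > 0`, `v` is concentrated on the
#' phenotype-associated taxa with alternating signs; otherwise it is dense
#' across all taxa.
#'
#' With `emulate_en300` set in the truth, the standardized trait is mapped
#' affinely to mean 75.32 and sd 17.5 and clipped to `[24, 129]`; clipping
#' touches < 0.5% of draws so variance shares are essentially preserved.
#'
#' @param truth a [simulation_truth()].
#' @param g the matching [genotype_matrix()].
#' @param otu the matching [mb_otu_table()].
#' @param site driving site for the microbial effect.
#' @return data.frame `bird_id`, `value`, with attribute `"components"`
#'   recording the realized shares and scaling.
#' @export
simulate_phenotype <- function(truth, g, otu, site = names(which.max(truth$true_m2))) {
  if (!site %in% otu$meta$site) stop_mb("site '%s' absent from OTU table", site)
  m2 <- unname(truth$true_m2[site])
  if (truth$true_h2 + m2 > 1)
    stop_mb("true_h2 + true_m2 share exceeds 1")
  birds <- rownames(g$calls)
  sub <- site_subset(otu, site)
  if (!identical(sort(sub$meta$bird_id), sort(birds)))
    stop_mb("OTU table and genotype matrix cover different birds")
  rel <- sub$counts / rowSums(sub$counts)
  rel <- rel[match(birds, sub$meta$bird_id), , drop = FALSE]
  arch <- attr(otu, "architecture")

  withr::with_seed(sub_seed(truth$seed, paste0("phenotype_", site)), {
    n <- length(birds)
    u <- if (truth$true_h2 > 0) {
      b <- stats::rnorm(ncol(g$calls))
      scale_to_share(as.numeric(scale(g$calls, scale = FALSE) %*% b), truth$true_h2)
    } else rep(0, n)

    v <- rep(0, n)
    if (m2 > 0) {
      sds <- apply(rel, 2, pop_sd)
      Z <- scale(rel[, sds > 0, drop = FALSE], scale = FALSE)
      Z <- sweep(Z, 2, sds[sds > 0], "/")
      w <- if (truth$n_assoc_taxa > 0 && length(arch$assoc_taxa)) {
        ww <- rep(0, ncol(Z))
        idx <- match(arch$assoc_taxa, colnames(rel)[sds > 0])
        ww[idx[!is.na(idx)]] <- arch$assoc_sign[!is.na(idx)]
        ww
      } else stats::rnorm(ncol(Z))
      v <- as.numeric(Z %*% w)
      if (truth$true_h2 > 0) v <- v - u * sum(v * u) / sum(u * u)
      v <- scale_to_share(v, m2)
    }
    e <- stats::rnorm(n)
    for (comp in list(u, v)) if (any(comp != 0))
      e <- e - comp * sum(e * comp) / sum(comp * comp)
    e <- scale_to_share(e, 1 - truth$true_h2 - m2)
    y <- u + v + e
    if (truth$emulate_en300) {
      y <- 75.32 + (y - mean(y)) / max(pop_sd(y), 1e-12) * 17.5
      y <- pmin(129, pmax(24, y))
    }
    out <- data.frame(bird_id = birds, value = as.numeric(y),
                      stringsAsFactors = FALSE)
    attr(out, "components") <- list(
      site = site, true_h2 = truth$true_h2, true_m2 = m2,
      realized_h2 = pop_var(u), realized_m2 = pop_var(v),
      en300_scale = truth$emulate_en300)
    out
  })
}

#' Simulate a random coalescent tree over OTU IDs
#'
#' @param otu_ids at least two leaf labels.
#' @param seed RNG seed.
#' @return A rooted [ape::phylo] tree with nonnegative branch lengths.
#' @export
simulate_tree <- function(otu_ids, seed = 1) {
  if (length(otu_ids) < 2) stop_mb("need at least 2 OTU IDs")
  withr::with_seed(seed, ape::rcoal(length(otu_ids), tip.label = otu_ids))
}

#' Write a complete simulated input bundle to disk
#'
#' Generates and writes everything the pipeline reads: a VCF, OTU count and
#' metadata TSVs, a newick tree, a phenotype TSV and a YAML truth manifest.
#' The `tiny` profile (8 birds, 20 SNPs, 10 OTUs) is for smoke tests; the
#' `paper_scale` profile is the full simulated study (128 birds x 6 sites,
#' 5,000 SNPs, 500 OTUs, EN300-scale phenotype).
#'
#' @param profile_name `"tiny"` or `"paper_scale"`.
#' @param seed master seed; byte-identical output for identical
#'   `(profile, seed)`.
#' @param dir output directory (created if needed).
#' @return Named list of file paths plus the `simulation_truth`, invisibly.
#' @export
make_fixture_bundle <- function(profile_name, seed, dir = tempfile("bundle_")) {
  truth <- switch(profile_name,
    tiny = simulation_truth(seed, n_birds = 12, n_snps = 20, n_otus = 10,
                            sites = c("crop", "isthmus"),
                            true_h2 = 0.282, true_m2 = c(isthmus = 0.6),
                            family_size = 4, n_heritable_taxa = 2,
                            snps_per_taxon = 5, emulate_en300 = TRUE),
    paper_scale = simulation_truth(seed, emulate_en300 = TRUE),
    stop_mb("unknown profile '%s' (profiles: tiny, paper_scale)", profile_name))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genotypes(truth$n_birds, truth$n_snps, truth$maf_range,
                          seed = sub_seed(truth$seed, "genotypes"),
                          n_families = ceiling(truth$n_birds / truth$family_size))
  otu <- simulate_otu_table(truth, g)
  tree <- simulate_tree(colnames(otu$counts), sub_seed(truth$seed, "tree"))
  pheno <- simulate_phenotype(truth, g, otu)

  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                otu = file.path(dir, "otu_counts.tsv"),
                meta = file.path(dir, "sample_meta.tsv"),
                tree = file.path(dir, "otu_tree.nwk"),
                pheno = file.path(dir, "phenotype.tsv"),
                truth = file.path(dir, "truth.yaml"))
  write_vcf(g, paths$vcf)
  write_otu_table(otu, paths$otu, paths$meta)
  ape::write.tree(tree, paths$tree)
  write_tsv_mb(pheno, paths$pheno)
  arch <- attr(otu, "architecture")
  comp <- attr(pheno, "components")
  yaml::write_yaml(list(
    profile = profile_name, seed = truth$seed,
    n_birds = truth$n_birds, n_snps = truth$n_snps, n_otus = truth$n_otus,
    sites = truth$sites, true_h2 = truth$true_h2,
    true_m2 = as.list(truth$true_m2), driving_site = comp$site,
    family_size = truth$family_size,
    heritable_taxa = arch$heritable_taxa, assoc_taxa = arch$assoc_taxa,
    emulate_en300 = truth$emulate_en300,
    abundance_model = paste("log-normal latent abundances with multinomial",
                            "sampling; a modeling stand-in, not a fitted",
                            "16S error profile")), paths$truth)
  invisible(c(paths, list(truth = truth)))
}
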
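#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Defaults are the standard
#' analysis parameters: rarefaction to the minimum sample depth, 20%
#' prevalence filter, 0.20/0.60 dichotomization breakpoints, 10,000
#' permutations, alpha 0.05, genome-wide threshold 1e-6, 5 genotype PCs
#' plus 2 significant-SNP PCs. Unknown keys are errors, not warnings.
#'
#' @param vcf,otu_counts,sample_meta,phenotype input paths (required).
#' @param tree optional newick path (enables UniFrac).
#' @param out_dir output directory.
#' @param sites site labels to analyze (`NULL` = every site in the metadata).
#' @param rarefaction_depth integer or `"min"`.
#' @param prevalence_min prevalence filter threshold.
#' @param dichotomize_breaks length-2: exclusion and binary breakpoints.
#' @param n_perm permutation count for ANOSIM/Mantel.
#' @param alpha significance level.
#' @param gwas_threshold genome-wide significance threshold.
#' @param n_genetic_pcs,n_snp_pcs covariate PC counts.
#' @param mrm_mode `"rarefied_counts"` or `"relative"`.
#' @param seed master seed; each stage derives its own sub-seed.
#' @param ... unknown keys (an error).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, otu_counts, sample_meta, phenotype,
                            tree = NULL, out_dir = tempfile("mb_run_"),
                            sites = NULL, rarefaction_depth = "min",
                            prevalence_min = 0.20,
                            dichotomize_breaks = c(0.20, 0.60),
                            n_perm = 10000, alpha = 0.05,
                            gwas_threshold = 1e-6,
                            n_genetic_pcs = 5, n_snp_pcs = 2,
                            mrm_mode = "rarefied_counts", seed = 1, ...) {
  extra <- list(...)
  if (length(extra))
    stop_mb("unknown configuration key(s): %s", paste(names(extra), collapse = ", "))
  assert_fraction(prevalence_min, "prevalence_min")
  assert_fraction(alpha, "alpha")
  if (length(dichotomize_breaks) != 2 ||
      dichotomize_breaks[1] >= dichotomize_breaks[2])
    stop_mb("dichotomize_breaks must be two increasing fractions")
  if (n_perm < 1) stop_mb("n_perm must be positive")
  structure(list(vcf = vcf, otu_counts = otu_counts, sample_meta = sample_meta,
                 phenotype = phenotype, tree = tree, out_dir = out_dir,
                 sites = sites, rarefaction_depth = rarefaction_depth,
                 prevalence_min = prevalence_min,
                 dichotomize_breaks = dichotomize_breaks, n_perm = n_perm,
                 alpha = alpha, gwas_threshold = gwas_threshold,
                 n_genetic_pcs = n_genetic_pcs, n_snp_pcs = n_snp_pcs,
                 mrm_mode = mrm_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full variance-partitioning pipeline
#'
#' Executes the eleven analysis stages in order — variant QC;
#' rarefaction and prevalence filtering; alpha/beta diversity with PCoA;
#' ANOSIM across sites; GRM and per-site MRMs; Mantel tests of GRM against
#' Bray-Curtis per site; trait h2; the LMM association scan with
#' significant-SNP PCs; per-site trait m2; the per-site taxon heritability
#' screen; and the trait-association overlap screen — writing every
#' intermediate as TSV plus a YAML manifest of parameters, stage seeds and
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the key results (`h2`, `m2` table,
#'   `anosim`, `mantel` table, screen tallies) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  outp <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop_mb("stage '%s' failed: %s (check the inputs this stage names)",
              name, conditionMessage(e)))
    stages <<- c(stages, name)
    res
  }

  # -- qc ------------------------------------------------------------------
  g <- stage("qc", {
    g0 <- read_vcf(config$vcf)
    filter_variants(g0)
  })
  pheno <- read_phenotypes(config$phenotype)
  otu_raw <- read_otu_table(config$otu_counts, config$sample_meta)
  if (!is.null(config$sites)) {
    keep <- otu_raw$meta$site %in% config$sites
    otu_raw <- mb_otu_table(otu_raw$counts[keep, , drop = FALSE],
                            otu_raw$meta[keep, ])
  }
  sites <- config$sites %||% sort(unique(otu_raw$meta$site))

  # -- rarefy_filter -------------------------------------------------------
  otu <- stage("rarefy_filter", {
    r <- rarefy(otu_raw, config$rarefaction_depth,
                seed = sub_seed(config$seed, "rarefy"))
    f <- prevalence_filter(r, config$prevalence_min)
    write_otu_table(f, outp("otu_rarefied_filtered.tsv"), outp("sample_meta.tsv"))
    f
  })

  # -- diversity -----------------------------------------------------------
  div <- stage("diversity", {
    alpha <- alpha_diversity(otu)
    write_tsv_mb(alpha, outp("alpha_diversity.tsv"))
    bc <- bray_curtis(otu)
    write_tsv_mb(as.matrix(bc), outp("bray_curtis.tsv"), row_label = "sample_id")
    ord <- pcoa(bc, k = 2)
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates,
                         explained_1 = ord$explained[1],
                         explained_2 = ord$explained[2])
    write_tsv_mb(coords, outp("pcoa.tsv"))
    uni <- NULL
    if (!is.null(config$tree)) {
      tree <- read_tree(config$tree)
      uni <- list(unweighted = unifrac(otu, tree, weighted = FALSE),
                  weighted = unifrac(otu, tree, weighted = TRUE))
      write_tsv_mb(as.matrix(uni$unweighted), outp("unweighted_unifrac.tsv"),
                   row_label = "sample_id")
      write_tsv_mb(as.matrix(uni$weighted), outp("weighted_unifrac.tsv"),
                   row_label = "sample_id")
    }
    list(alpha = alpha, bc = bc, pcoa = ord, unifrac = uni)
  })

  # -- anosim --------------------------------------------------------------
  ano <- stage("anosim", {
    a <- anosim(div$bc, otu$meta$site, n_perm = config$n_perm,
                seed = sub_seed(config$seed, "anosim"))
    write_tsv_mb(data.frame(statistic_R = a$statistic, p_value = a$p_value,
                            n_perm = a$n_perm), outp("anosim.tsv"))
    a
  })

  # -- relmat --------------------------------------------------------------
  rel <- stage("relmat", {
    grm <- compute_grm(g)
    write_relationship_matrix(grm, outp("grm.tsv"))
    mrms <- lapply(sites, function(s) {
      m <- suppressWarnings(compute_mrm(otu, s, abundance_mode = config$mrm_mode))
      write_relationship_matrix(m, outp(sprintf("mrm_%s.tsv", s)))
      m
    })
    names(mrms) <- sites
    list(grm = grm, mrms = mrms)
  })

  # -- mantel --------------------------------------------------------------
  man <- stage("mantel", {
    rows <- lapply(sites, function(s) {
      sub <- site_subset(otu, s)
      ids <- sub$meta$bird_id
      bcs <- as.matrix(bray_curtis(sub))
      dimnames(bcs) <- list(ids, ids)     # per-site samples relabeled by bird
      gsub_ <- rel$grm$mat[ids, ids]
      out <- lapply(c("pearson", "spearman"), function(meth)
        mantel(gsub_, bcs, method = meth, n_perm = config$n_perm,
               seed = sub_seed(config$seed, paste0("mantel_", s, meth))))
      data.frame(site = s, method = c("pearson", "spearman"),
                 r = vapply(out, `[[`, 0, "statistic"),
                 p = vapply(out, `[[`, 0, "p_value"))
    })
    tab <- do.call(rbind, rows)
    write_tsv_mb(tab, outp("mantel_grm_bc.tsv"))
    tab
  })

  # -- h2 ------------------------------------------------------------------
  h2 <- stage("h2", {
    fit <- estimate_h2(pheno, rel$grm, n_pcs = config$n_genetic_pcs)
    write_tsv_mb(data.frame(h2 = fit$ratio, se = fit$se_ratio,
                            lrt_p = fit$lrt_p, n = fit$n), outp("h2.tsv"))
    fit
  })

  # -- gwas ----------------------------------------------------------------
  gen_pcs <- genotype_pca(rel$grm, k = config$n_genetic_pcs)$coordinates
  gwas <- stage("gwas", {
    scan <- lmm_gwas_scan(pheno, g, rel$grm, covariates = gen_pcs)
    write_tsv_mb(scan$results, outp("gwas.tsv"))
    scan
  })
  snp_pcs <- withCallingHandlers(
    significant_snp_pcs(gwas, g, p_threshold = config$gwas_threshold,
                        k = config$n_snp_pcs),
    warning = function(w) invokeRestart("muffleWarning"))

  # -- m2 ------------------------------------------------------------------
  m2 <- stage("m2", {
    rows <- lapply(sites, function(s) {
      fit <- estimate_m2(pheno, rel$mrms[[s]], genetic_pcs = gen_pcs,
                         snp_pcs = snp_pcs)
      data.frame(site = s, m2 = fit$ratio, se = fit$se_ratio,
                 lrt_p = fit$lrt_p, n = fit$n)
    })
    tab <- do.call(rbind, rows)
    write_tsv_mb(tab, outp("m2.tsv"))
    tab
  })

  # -- heritability_screen -------------------------------------------------
  her <- stage("heritability_screen", {
    tabs <- lapply(sites, function(s)
      taxon_heritability_screen(otu, s, rel$grm, alpha = config$alpha,
                                n_pcs = config$n_genetic_pcs))
    names(tabs) <- sites
    all_tab <- do.call(rbind, Map(function(t, s) cbind(site = s, t), tabs, sites))
    write_tsv_mb(all_tab, outp("heritability_screen.tsv"))
    tabs
  })

  # -- en300_screen --------------------------------------------------------
  en <- stage("en300_screen", {
    tabs <- lapply(sites, function(s)
      en300_microbe_screen(otu, s, pheno, alpha = config$alpha))
    names(tabs) <- sites
    all_tab <- do.call(rbind, Map(function(t, s) cbind(site = s, t), tabs, sites))
    write_tsv_mb(all_tab, outp("en300_screen.tsv"))
    tabs
  })

  summary_tab <- data.frame(
    site = sites,
    n_taxa_heritable = vapply(her, function(t) sum(t$heritable), 0L),
    cumulative_heritable_abundance =
      vapply(sites, function(s) cumulative_heritable_abundance(her[[s]], otu, s), 0),
    n_taxa_associated = vapply(en, function(t) sum(t$pass), 0L))
  write_tsv_mb(summary_tab, outp("screen_summary.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("microbiability")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "out_dir")],
    stages = as.list(stages),
    outputs = as.list(list.files(config$out_dir, pattern = "\\.tsv$")))
  yaml::write_yaml(manifest, outp("manifest.yaml"))

  invisible(list(out_dir = config$out_dir, stages = stages, h2 = h2, m2 = m2,
                 anosim = ano, mantel = man, heritability_screen = her,
                 en300_screen = en, screen_summary = summary_tab,
                 pcoa_explained = div$pcoa$explained))
}

#' One-page summary report of a pipeline run
#'
#' Reads the result bundle in `out_dir` and renders a deterministic
#' markdown summary: diversity per site, ANOSIM, Mantel rows, h2 with its
#' LRT p, the per-site m2 table, and the screen tallies. Missing outputs are
#' flagged as gaps rather than failing.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path optional file to write the report to.
#' @return The report as a character vector of lines, invisibly if `path`
#'   is given.
#' @export
report <- function(out_dir, path = NULL) {
  rd <- function(name) {
    f <- file.path(out_dir, name)
    if (file.exists(f)) read_tsv_mb(f) else NULL
  }
  fmt <- function(x, digits = 3) formatC(as.numeric(x), digits = digits, format = "f")
  lines <- c("# Variance-partitioning pipeline report", "")
  man <- file.path(out_dir, "manifest.yaml")
  if (file.exists(man)) {
    m <- yaml::read_yaml(man)
    lines <- c(lines, sprintf("Seed %d; stages run: %s.", m$seed,
                              paste(unlist(m$stages), collapse = ", ")), "")
  } else lines <- c(lines, "[gap] manifest.yaml missing", "")

  alpha <- rd("alpha_diversity.tsv"); meta <- rd("sample_meta.tsv")
  if (!is.null(alpha) && !is.null(meta)) {
    alpha$site <- meta$site[match(alpha$sample_id, meta$sample_id)]
    agg <- stats::aggregate(cbind(observed_otus, chao1, shannon, simpson) ~ site,
                            alpha, mean)
    lines <- c(lines, "## Alpha diversity (site means)", "",
               "site | observed | chao1 | shannon | simpson",
               "---- | -------- | ----- | ------- | -------",
               sprintf("%s | %s | %s | %s | %s", agg$site,
                       fmt(agg$observed_otus, 1), fmt(agg$chao1, 1),
                       fmt(agg$shannon), fmt(agg$simpson)), "")
  } else lines <- c(lines, "[gap] alpha diversity missing", "")

  pc <- rd("pcoa.tsv")
  if (!is.null(pc))
    lines <- c(lines, sprintf(
      "PCoA of Bray-Curtis: axis 1 explains %s%%, axis 2 %s%%.",
      fmt(100 * pc$explained_1[1], 2), fmt(100 * pc$explained_2[1], 2)), "")

  an <- rd("anosim.tsv")
  if (!is.null(an))
    lines <- c(lines, sprintf("ANOSIM across sites: R = %s, p = %.3g (%d permutations).",
                              fmt(an$statistic_R), an$p_value, an$n_perm), "")

  mt <- rd("mantel_grm_bc.tsv")
  if (!is.null(mt)) {
    lines <- c(lines, "## Mantel: GRM vs Bray-Curtis per site", "",
               "site | method | r | p", "---- | ------ | - | -",
               sprintf("%s | %s | %s | %.3g", mt$site, mt$method, fmt(mt$r), mt$p), "")
  }

  h2 <- rd("h2.tsv")
  if (!is.null(h2)) {
    lines <- c(lines, sprintf("## Heritability of the trait: h2 = %s (SE %s), LRT p = %.3g",
                              fmt(h2$h2), fmt(h2$se), h2$lrt_p), "")
  } else lines <- c(lines, "[gap] h2 missing", "")

  m2 <- rd("m2.tsv")
  if (!is.null(m2)) {
    lines <- c(lines, "## Microbiability per site", "",
               "site | m2 | SE | LRT p", "---- | -- | -- | -----",
               sprintf("%s | %s | %s | %.3g", m2$site, fmt(m2$m2),
                       fmt(m2$se), m2$lrt_p), "")
  } else lines <- c(lines, "[gap] m2 missing", "")

  sc <- rd("screen_summary.tsv")
  if (!is.null(sc)) {
    lines <- c(lines, "## Screens", "",
               "site | heritable taxa | cumulative abundance | trait-associated taxa",
               "---- | -------------- | -------------------- | ---------------------",
               sprintf("%s | %d | %s | %d", sc$site, sc$n_taxa_heritable,
                       fmt(sc$cumulative_heritable_abundance, 4),
                       sc$n_taxa_associated), "")
  } else lines <- c(lines, "[gap] screen summary missing", "")

  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
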
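#' Analysis mode from taxon prevalence
#'
#' The prevalence-based dichotomization rule: taxa present in fewer than 20%
#' of a site's samples are excluded; in at least 20% but fewer than 60%,
#' analyzed as a presence/absence (binary) trait; at 60% or more, as a
#' quantitative abundance trait. Boundaries are exactly 0.20 and 0.60, both
#' inclusive on the upper side.
#'
#' @param prevalence fraction(s) in `[0, 1]`.
#' @param exclude_below,binary_below the two breakpoints.
#' @return Character vector: `"excluded"`, `"binary"` or `"quantitative"`.
#' @export
assign_mode <- function(prevalence, exclude_below = 0.20, binary_below = 0.60) {
  if (any(prevalence < 0 | prevalence > 1)) stop_mb("prevalence must be in [0, 1]")
  ifelse(prevalence < exclude_below, "excluded",
         ifelse(prevalence < binary_below, "binary", "quantitative"))
}

# aggregate OTU counts to a coarser taxonomic level by summing members
aggregate_taxa <- function(otu, taxonomy = NULL) {
  if (is.null(taxonomy)) return(otu)
  if (!all(c("otu_id", "taxon") %in% names(taxonomy)))
    stop_mb("taxonomy needs columns otu_id, taxon")
  tx <- taxonomy$taxon[match(colnames(otu$counts), taxonomy$otu_id)]
  if (anyNA(tx)) stop_mb("taxonomy missing for %d OTU(s)", sum(is.na(tx)))
  agg <- t(rowsum(t(otu$counts), tx))
  mb_otu_table(agg, otu$meta)
}

#' Per-taxon SNP-based heritability screen
#'
#' For each taxon at one site: compute prevalence and assign the analysis
#' mode with [assign_mode()]; fit the heritability model with the taxon's
#' standardized abundance (quantitative mode) or its 0/1 presence indicator
#' on the observed scale (binary mode) as the trait; test the variance
#' component with the REML likelihood-ratio test. Taxa below 20% prevalence
#' are excluded. A taxon is called heritable when its LRT p is below
#' `alpha`.
#'
#' Fitting a variance component is the principled significance test here;
#' the field sometimes reports such screens under rank-test labels, but a
#' rank test does not address a variance component, so the REML LRT is used
#' throughout.
#'
#' @param otu an [mb_otu_table()] (counts as analyzed, typically rarefied).
#' @param site body site.
#' @param grm GRM over the birds at the site.
#' @param taxonomy optional data.frame `otu_id`, `taxon` to aggregate OTUs
#'   to a coarser level (counts summed before analysis).
#' @param alpha significance level (default 0.05).
#' @param n_pcs genotype PCs used as fixed covariates.
#' @return data.frame, one row per taxon: `taxon`, `prevalence`, `mode`,
#'   `h2`, `se`, `lrt_p`, `heritable`; class `mb_screen`.
#' @export
taxon_heritability_screen <- function(otu, site, grm, taxonomy = NULL,
                                      alpha = 0.05, n_pcs = 5) {
  otu <- aggregate_taxa(otu, taxonomy)
  sub <- site_subset(otu, site)
  if (!all(sub$meta$bird_id %in% grm$ids))
    stop_mb("GRM does not cover every bird at site '%s'", site)
  ord <- match(grm$ids, sub$meta$bird_id)
  if (anyNA(ord)) {
    keep <- grm$ids %in% sub$meta$bird_id
    stop_mb("GRM has %d bird(s) not sampled at site '%s'", sum(!keep), site)
  }
  cnt <- sub$counts[ord, , drop = FALSE]
  n <- nrow(cnt)
  prev <- colMeans(cnt > 0)
  mode <- assign_mode(prev)
  Keig <- eigen(grm$mat, symmetric = TRUE)
  X <- cbind(1, genotype_pca(grm, k = min(n_pcs, n - 2))$coordinates)
  res <- data.frame(taxon = colnames(cnt), prevalence = prev, mode = mode,
                    h2 = NA_real_, se = NA_real_, lrt_p = NA_real_,
                    heritable = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (j in which(mode != "excluded")) {
    yj <- if (mode[j] == "quantitative") as.numeric(scale(cnt[, j]))
          else as.numeric(cnt[, j] > 0)
    if (stats::sd(yj) == 0) { res$mode[j] <- "excluded"; next }
    fit <- tryCatch(reml_single_component(yj, grm, X = X, Keig = Keig),
                    error = function(e) NULL)
    if (is.null(fit)) next
    res$h2[j] <- fit$ratio
    res$se[j] <- fit$se_ratio
    res$lrt_p[j] <- fit$lrt_p
    res$heritable[j] <- fit$lrt_p < alpha
  }
  attr(res, "site") <- site
  attr(res, "alpha") <- alpha
  class(res) <- c("mb_screen", class(res))
  res
}

#' Cumulative relative abundance of the heritable taxa
#'
#' Sum over taxa flagged heritable of their mean within-sample relative
#' abundance at the site; with all taxa heritable this is 1.
#'
#' @param screen result of [taxon_heritability_screen()].
#' @param otu the OTU table the screen was computed on.
#' @param site body site.
#' @param taxonomy the same aggregation used for the screen, if any.
#' @return A fraction in `[0, 1]`.
#' @export
cumulative_heritable_abundance <- function(screen, otu, site, taxonomy = NULL) {
  otu <- aggregate_taxa(otu, taxonomy)
  sub <- site_subset(otu, site)
  rel <- sub$counts / rowSums(sub$counts)
  her <- screen$taxon[screen$heritable]
  if (!length(her)) return(0)
  sum(colMeans(rel[, her, drop = FALSE]))
}

#' Extreme phenotype groups
#'
#' Bottom and top `floor(fraction * n)` birds by phenotype; ties at either
#' cut are broken by stable bird-ID order so the grouping is deterministic.
#'
#' @param pheno data.frame `bird_id`, `value` with `n >= 10`.
#' @param fraction group fraction, below 0.5.
#' @return List `low`, `high` (bird IDs), `fraction`, `size`.
#' @export
extreme_groups <- function(pheno, fraction = 0.2) {
  if (fraction >= 0.5) stop_mb("fraction must be < 0.5")
  n <- nrow(pheno)
  if (n < 10) stop_mb("need at least 10 birds")
  k <- floor(fraction * n)
  if (k < 1) stop_mb("fraction too small for n = %d", n)
  ord <- order(pheno$value, pheno$bird_id)
  list(low = pheno$bird_id[ord[seq_len(k)]],
       high = pheno$bird_id[rev(ord)[seq_len(k)]],
       fraction = fraction, size = k)
}

#' Three-way overlap screen for trait-associated taxa
#'
#' Applies the three criteria of the egg-production association screen to
#' every taxon passing the 20% prevalence filter at one site:
#' \enumerate{
#'   \item Wilcoxon rank-sum test of abundance between the bottom- and
#'     top-`fraction` phenotype groups, requiring raw `p < alpha` AND
#'     BH-FDR `< alpha`;
#'   \item Pearson correlation of abundance with the phenotype across all
#'     birds, BH-adjusted `p < alpha`;
#'   \item Spearman correlation (Z-test), BH-adjusted `p < alpha`.
#' }
#' A taxon passes only if all three hold; the association sign is the sign
#' of the Pearson r. BH adjustment is performed within the family of all
#' taxa tested at this (site, level).
#'
#' @param otu an [mb_otu_table()] (rarefied counts).
#' @param site body site.
#' @param pheno data.frame `bird_id`, `value`.
#' @param taxonomy optional aggregation map (`otu_id`, `taxon`).
#' @param alpha significance level.
#' @param fraction extreme-group fraction.
#' @return data.frame per taxon: prevalence, wilcoxon p/FDR, pearson and
#'   spearman r and adjusted p, `pass`, `sign`; class `mb_screen`.
#' @export
en300_microbe_screen <- function(otu, site, pheno, taxonomy = NULL,
                                 alpha = 0.05, fraction = 0.2) {
  otu <- aggregate_taxa(otu, taxonomy)
  sub <- site_subset(otu, site)
  keep <- pheno$bird_id %in% sub$meta$bird_id
  pheno <- pheno[keep, , drop = FALSE]
  rel <- sub$counts / rowSums(sub$counts)
  rel <- rel[match(pheno$bird_id, sub$meta$bird_id), , drop = FALSE]
  prev <- colMeans(rel > 0)
  tested <- which(prev >= 0.20)
  if (!length(tested)) stop_mb("no taxon reaches 20%% prevalence at site '%s'", site)
  grp <- extreme_groups(pheno, fraction)
  lo <- match(grp$low, pheno$bird_id); hi <- match(grp$high, pheno$bird_id)
  y <- pheno$value
  res <- data.frame(taxon = colnames(rel)[tested],
                    prevalence = prev[tested],
                    wilcoxon_p = NA_real_, wilcoxon_fdr = NA_real_,
                    pearson_r = NA_real_, pearson_adj_p = NA_real_,
                    spearman_r = NA_real_, spearman_adj_p = NA_real_,
                    pass = FALSE, sign = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(tested)) {
    a <- rel[, tested[i]]
    res$wilcoxon_p[i] <- suppressWarnings(wilcoxon_rank_sum(a[lo], a[hi])$p_value)
    if (stats::sd(a) > 0) {
      pe <- correlation_test(a, y, "pearson")
      sp <- correlation_test(a, y, "spearman")
      res$pearson_r[i] <- pe$r; res$pearson_adj_p[i] <- pe$p_value
      res$spearman_r[i] <- sp$r; res$spearman_adj_p[i] <- sp$p_value
    }
  }
  res$wilcoxon_fdr <- bh_adjust(res$wilcoxon_p)
  ok <- !is.na(res$pearson_adj_p)
  res$pearson_adj_p[ok] <- bh_adjust(res$pearson_adj_p[ok])
  res$spearman_adj_p[ok] <- bh_adjust(res$spearman_adj_p[ok])
  res$pass <- !is.na(res$pearson_adj_p) &
    res$wilcoxon_p < alpha & res$wilcoxon_fdr < alpha &
    res$pearson_adj_p < alpha & res$spearman_adj_p < alpha
  res$sign <- sign(res$pearson_r)
  attr(res, "site") <- site
  attr(res, "alpha") <- alpha
  attr(res, "adjustment_family") <- sprintf("site=%s;n_taxa=%d", site, nrow(res))
  class(res) <- c("mb_screen", class(res))
  res
}

#' Phenotype contrast between extreme-abundance groups of one taxon
#'
#' Forms the bottom- and top-`fraction` groups of birds BY the taxon's
#' abundance (not by phenotype) and compares their mean phenotype with the
#' two-sided permutation test.
#'
#' @param otu an [mb_otu_table()].
#' @param site body site.
#' @param taxon taxon (column) name.
#' @param pheno data.frame `bird_id`, `value`.
#' @param fraction extreme-group fraction.
#' @param n_perm,seed permutation settings.
#' @return An `mb_perm_test` with the two group means attached.
#' @export
extreme_abundance_phenotype_compare <- function(otu, site, taxon, pheno,
                                                fraction = 0.2,
                                                n_perm = 10000, seed = 1) {
  sub <- site_subset(otu, site)
  if (!taxon %in% colnames(sub$counts))
    stop_mb("taxon '%s' not present at site '%s'", taxon, site)
  rel <- sub$counts[, taxon] / rowSums(sub$counts)
  if (stats::sd(rel) == 0)
    stop_mb("taxon '%s' has constant abundance: grouping undefined", taxon)
  ab <- data.frame(bird_id = sub$meta$bird_id, value = rel,
                   stringsAsFactors = FALSE)
  grp <- extreme_groups(ab, fraction)
  y <- pheno$value[match(c(grp$low, grp$high), pheno$bird_id)]
  if (anyNA(y)) stop_mb("phenotype missing for some grouped birds")
  ylo <- y[seq_len(grp$size)]; yhi <- y[-seq_len(grp$size)]
  out <- permutation_mean_test(yhi, ylo, n_perm = n_perm, seed = seed)
  out$mean_high <- mean(yhi); out$mean_low <- mean(ylo)
  out$taxon <- taxon
  out
}
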
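#' Relationship matrix container
#'
#' Symmetric individuals-by-individuals similarity matrix: a GRM built from
#' reference-allele dosages or an MRM built from standardized OTU abundances
#' at one body site.
#'
#' @param mat symmetric numeric matrix with IDs as dimnames.
#' @param kind `"GRM"` or `"MRM"`.
#' @param n_features number of SNPs (`N`) or OTUs (`N_T`) used.
#' @param site body site (MRM only).
#' @return Object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(mat, kind, n_features, site = NULL) {
  mat <- (mat + t(mat)) / 2                      # exact symmetry
  if (!all(is.finite(mat))) stop_mb("relationship matrix has non-finite entries")
  structure(list(mat = mat, ids = rownames(mat), kind = kind,
                 n_features = n_features, site = site),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s over %d individuals (%d features%s); mean diagonal %.4f\n",
              x$kind, nrow(x$mat), x$n_features,
              if (is.null(x$site)) "" else paste0(", site ", x$site),
              mean(diag(x$mat))))
  invisible(x)
}

#' @export
as.matrix.relationship_matrix <- function(x, ...) x$mat

#' Genomic relatedness matrix from reference-allele dosages
#'
#' `h_ij = (1/N) sum_a (r_ia - 2 f_a)(r_ja - 2 f_a) / (2 f_a (1 - f_a))`,
#' where `r` counts reference alleles and `f_a` is the sample frequency of
#' the reference allele. Monomorphic SNPs make the denominator zero and are
#' an error (they should have been removed by QC).
#'
#' @param g a [genotype_matrix()] with at least 2 individuals; missing calls
#'   must already be imputed (see [filter_variants()]).
#' @return A `relationship_matrix` of kind `"GRM"`.
#' @export
compute_grm <- function(g) {
  calls <- g$calls
  if (nrow(calls) < 2) stop_mb("need at least 2 individuals")
  if (anyNA(calls)) stop_mb("missing calls present; run filter_variants() first")
  f <- colMeans(calls) / 2
  mono <- f <= 0 | f >= 1
  if (any(mono))
    stop_mb("monomorphic SNP(s) reach the GRM: %s",
            paste(colnames(calls)[mono], collapse = ", "))
  z <- sweep(calls, 2, 2 * f)
  z <- sweep(z, 2, sqrt(2 * f * (1 - f)), "/")
  relationship_matrix(tcrossprod(z) / ncol(calls), "GRM", ncol(calls))
}

#' Microbial relationship matrix at one body site
#'
#' `r_tij = (1/N_T) sum_o (a_tio - abar_to)(a_tjo - abar_to) / var_to`: the
#' mean cross-product of abundances standardized per OTU to zero mean and
#' unit variance across the birds sampled at the site. Standardization uses
#' the population variance (divisor n), which forces the mean diagonal to be
#' exactly 1 (a `sample` variance switch is provided since either convention
#' is seen in practice). Zero-variance OTUs are dropped with a warning.
#'
#' @param otu an [mb_otu_table()].
#' @param site body site.
#' @param abundance_mode `"rarefied_counts"` to standardize the (rarefied)
#'   counts as-is, or `"relative"` to convert to within-sample relative
#'   abundance first.
#' @param variance `"population"` (divisor n, default) or `"sample"`
#'   (divisor n-1).
#' @return A `relationship_matrix` of kind `"MRM"`, ordered by bird ID.
#' @export
compute_mrm <- function(otu, site,
                        abundance_mode = c("rarefied_counts", "relative"),
                        variance = c("population", "sample")) {
  abundance_mode <- match.arg(abundance_mode)
  variance <- match.arg(variance)
  sub <- site_subset(otu, site)
  a <- sub$counts
  if (nrow(a) < 2) stop_mb("need at least 2 birds sampled at site '%s'", site)
  if (abundance_mode == "relative") a <- a / rowSums(a)
  n <- nrow(a)
  ctr <- scale(a, scale = FALSE)
  v <- colMeans(ctr^2)
  if (variance == "sample") v <- v * n / (n - 1)
  drop <- v <= 0
  if (all(drop)) stop_mb("every OTU has zero variance at site '%s'", site)
  if (any(drop))
    warn_mb("dropped %d zero-variance OTU(s) at site '%s'", sum(drop), site)
  z <- sweep(ctr[, !drop, drop = FALSE], 2, sqrt(v[!drop]), "/")
  mat <- tcrossprod(z) / ncol(z)
  dimnames(mat) <- list(sub$meta$bird_id, sub$meta$bird_id)
  relationship_matrix(mat, "MRM", ncol(z), site = site)
}

#' Greedy LD pruning
#'
#' Sliding-window removal of correlated SNPs, in the style of
#' `indep-pairwise`: within each window (of `window_kb` kilobases, advanced
#' by `step_snps` SNPs), while any pair of retained SNPs has squared dosage
#' correlation above `r2_max`, the member of the worst pair with the lower
#' MAF is removed (ties: the later position). Pruning a pruned set removes
#' nothing. The conventional parameters are 50 kb, 10 SNPs, r2 0.2.
#'
#' @param g a [genotype_matrix()] with sorted positions (the constructor
#'   enforces this).
#' @param window_kb window size in kilobases.
#' @param step_snps window advance in SNPs.
#' @param r2_max maximum allowed squared correlation.
#' @return The pruned [genotype_matrix()].
#' @export
ld_prune <- function(g, window_kb = 50, step_snps = 10, r2_max = 0.2) {
  calls <- g$calls
  if (anyNA(calls)) {        # mean-impute on the fly for correlation only
    for (j in which(colSums(is.na(calls)) > 0))
      calls[is.na(calls[, j]), j] <- mean(calls[, j], na.rm = TRUE)
  }
  m <- ncol(calls)
  f <- colMeans(calls) / 2
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, m)
  for (ch in unique(g$map$chrom)) {
    idx_ch <- which(g$map$chrom == ch)
    start <- 1
    while (start <= length(idx_ch)) {
      w0 <- idx_ch[start]
      in_win <- idx_ch[g$map$pos[idx_ch] >= g$map$pos[w0] &
                       g$map$pos[idx_ch] < g$map$pos[w0] + window_kb * 1000]
      repeat {
        act <- in_win[keep[in_win]]
        if (length(act) < 2) break
        cc <- suppressWarnings(stats::cor(calls[, act, drop = FALSE]))
        cc[!is.finite(cc)] <- 0
        diag(cc) <- 0
        r2 <- cc^2
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (max(r2) <= r2_max) break
        pair <- act[worst]
        victim <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                  else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                  else pair[which.max(g$map$pos[pair])]
        keep[victim] <- FALSE
      }
      start <- start + step_snps
    }
  }
  genotype_matrix(g$calls[, keep, drop = FALSE], g$map[keep, , drop = FALSE],
                  imputed = g$imputed)
}

#' Genotype principal components
#'
#' PCs are eigenvectors of the GRM scaled by the square roots of their
#' eigenvalues, in descending eigenvalue order. Sign convention: the
#' largest-magnitude loading of each PC is positive.
#'
#' @param x a [genotype_matrix()] or a precomputed GRM
#'   (`relationship_matrix`).
#' @param k number of components (`1 <= k <= n - 1`).
#' @return List with `coordinates` (n x k, rownames = IDs) and
#'   `eigenvalues` (all n).
#' @export
genotype_pca <- function(x, k = 5) {
  grm <- if (inherits(x, "relationship_matrix")) x else compute_grm(x)
  n <- nrow(grm$mat)
  if (k <= 0 || k > n - 1) stop_mb("k must be in 1..%d", n - 1)
  e <- eigen(grm$mat, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(grm$ids, paste0("PC", seq_len(k)))
  list(coordinates = coords, eigenvalues = e$values)
}

#' Write a relationship matrix as TSV
#'
#' Two formats: a square matrix with an ID header (`format = "square"`) or a
#' long `(id1, id2, value)` triple table over the lower triangle including
#' the diagonal (`format = "triples"`), convenient for interoperability with
#' GCTA-style tooling.
#'
#' @param rm a `relationship_matrix`.
#' @param path output path.
#' @param format `"square"` or `"triples"`.
#' @return `path`, invisibly.
#' @export
write_relationship_matrix <- function(rm, path, format = c("square", "triples")) {
  format <- match.arg(format)
  if (format == "square") {
    write_tsv_mb(rm$mat, path, row_label = "id")
  } else {
    idx <- which(lower.tri(rm$mat, diag = TRUE), arr.ind = TRUE)
    write_tsv_mb(data.frame(id1 = rm$ids[idx[, 1]], id2 = rm$ids[idx[, 2]],
                            value = rm$mat[idx]), path)
  }
  invisible(path)
}
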
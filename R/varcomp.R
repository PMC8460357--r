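#' @title Variance-component estimation
#' @description Restricted maximum likelihood for models with one
#'   relationship-structured random effect plus residual: the heritability
#'   model `y = Xc + g + e`, `g ~ N(0, G sigma2_A)` with `G` a GRM, and the
#'   microbiability model `y = Xc + m + e`, `m ~ N(0, M sigma2_m)` with `M`
#'   an MRM. Because both models have exactly one random effect plus
#'   residual, the restricted likelihood is profiled on the variance ratio
#'   after a single eigendecomposition of the relationship matrix (the
#'   EMMA-style spectral form), which is exact and fast.
#' @name varcomp
NULL

# restricted log-likelihood at ratio lambda = sigma2_u / sigma2_e,
# in the eigenbasis of K (d = eigenvalues, yt/Xt rotated data)
reml_profile_ll <- function(lambda, d, yt, Xt) {
  n <- length(yt); p <- ncol(Xt)
  w <- lambda * d + 1
  sw <- sqrt(w)
  q <- qr(Xt / sw)
  rss <- sum(qr.resid(q, yt / sw)^2)
  -0.5 * ((n - p) * (log(2 * pi) + 1) + (n - p) * log(rss / (n - p)) +
          sum(log(w)) + 2 * sum(log(abs(diag(qr.R(q))))))
}

# average-information matrix for (sigma2_u, sigma2_e) in the eigenbasis
reml_ai_se <- function(lambda, sigma2_e, d, yt, Xt) {
  v <- lambda * sigma2_e * d + sigma2_e
  apply_P <- function(b) {
    s <- b / v
    XtVi <- Xt / v
    s - XtVi %*% solve(crossprod(Xt, XtVi), crossprod(Xt, s))
  }
  py <- apply_P(yt)
  t1 <- d * py; t2 <- py
  ai <- matrix(c(sum(t1 * apply_P(t1)), sum(t1 * apply_P(t2)),
                 sum(t1 * apply_P(t2)), sum(t2 * apply_P(t2))) / 2, 2, 2)
  co <- solve(ai)
  s_u <- lambda * sigma2_e; s_p <- s_u + sigma2_e
  grad <- c(sigma2_e, -s_u) / s_p^2
  sqrt(max(0, drop(t(grad) %*% co %*% grad)))
}

#' REML for a single relationship-structured variance component
#'
#' Fits `y = Xc + u + e` with `u ~ N(0, K sigma2_u)`, `e ~ N(0, I sigma2_e)`
#' by profiling the restricted likelihood over `lambda = sigma2_u/sigma2_e`
#' on a log grid followed by bounded refinement, after one
#' eigendecomposition of `K`. Reports the variance ratio
#' `sigma2_u / (sigma2_u + sigma2_e)` (h2 when `K` is a GRM, m2 when an
#' MRM), a delta-method standard error from the inverse average-information
#' matrix, and a likelihood-ratio test of `sigma2_u = 0` against the
#' boundary mixture null `0.5*chisq(0) + 0.5*chisq(1)`.
#'
#' @param y numeric response vector.
#' @param K a `relationship_matrix` or symmetric PSD matrix aligned to `y`.
#' @param X fixed-effect design matrix (default intercept only); must have
#'   full column rank.
#' @param Keig optional precomputed `eigen(K)` (symmetric), reused when many
#'   traits share one relationship matrix.
#' @param lambda_range log10 search bounds for the variance ratio.
#' @return Object of class `varcomp_est`: `sigma2_u`, `sigma2_e`,
#'   `sigma2_p`, `ratio`, `se_ratio`, `lambda`, `loglik_full`, `loglik_null`,
#'   `lrt`, `lrt_p`, `n`.
#' @export
reml_single_component <- function(y, K, X = NULL, Keig = NULL,
                                  lambda_range = c(-5, 5)) {
  Km <- if (inherits(K, "relationship_matrix")) K$mat else (K + t(K)) / 2
  n <- length(y)
  if (nrow(Km) != n) stop_mb("K is %d x %d but y has length %d", nrow(Km), ncol(Km), n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop_mb("X is rank deficient")
  p <- ncol(X)
  if (n - p < 2) stop_mb("too few residual degrees of freedom")
  e <- Keig %||% eigen(Km, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop_mb("K is not positive semidefinite (min eigenvalue %.3g)", min(e$values))
  d <- pmax(e$values, 0)
  if (max(d) - min(d) < 1e-8 * max(1, max(d)))
    stop_mb("K is proportional to the identity: variance ratio unidentifiable")
  yt <- crossprod(e$vectors, y)[, 1]
  Xt <- crossprod(e$vectors, X)

  grid <- 10^seq(lambda_range[1], lambda_range[2], length.out = 61)
  lls <- vapply(grid, reml_profile_ll, 0, d = d, yt = yt, Xt = Xt)
  i <- which.max(lls)
  lo <- log10(grid[max(1, i - 1)]); hi <- log10(grid[min(length(grid), i + 1)])
  opt <- stats::optimize(function(l) reml_profile_ll(10^l, d, yt, Xt),
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- 10^opt$maximum
  ll_full <- opt$objective
  ll_null <- reml_profile_ll(0, d, yt, Xt)
  if (ll_null >= ll_full) { lambda <- 0; ll_full <- ll_null }

  w <- lambda * d + 1
  sw <- sqrt(w)
  q <- qr(Xt / sw)
  rss <- sum(qr.resid(q, yt / sw)^2)
  sigma2_e <- rss / (n - p)
  sigma2_u <- lambda * sigma2_e
  ratio <- if (lambda == 0) 0 else lambda / (1 + lambda)
  se <- tryCatch(
    if (lambda > 0) reml_ai_se(lambda, sigma2_e, d, yt, Xt) else NA_real_,
    error = function(e) NA_real_)
  lrt <- max(0, 2 * (ll_full - ll_null))
  lrt_p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 sigma2_p = sigma2_u + sigma2_e, ratio = ratio,
                 se_ratio = se, lambda = lambda,
                 loglik_full = ll_full, loglik_null = ll_null,
                 lrt = lrt, lrt_p = lrt_p, n = n),
            class = "varcomp_est")
}

#' @export
print.varcomp_est <- function(x, ...) {
  cat(sprintf("variance ratio = %.4f (SE %s), sigma2_u = %.4g, sigma2_e = %.4g\n",
              x$ratio, ifelse(is.na(x$se_ratio), "NA", sprintf("%.4f", x$se_ratio)),
              x$sigma2_u, x$sigma2_e))
  cat(sprintf("LRT = %.3f, p = %.4g (boundary mixture null), n = %d\n",
              x$lrt, x$lrt_p, x$n))
  invisible(x)
}

align_pheno <- function(pheno, ids) {
  common <- intersect(ids, pheno$bird_id)
  if (length(common) < length(ids))
    stop_mb("%d individual(s) in the relationship matrix lack phenotypes",
            length(ids) - length(common))
  pheno$value[match(ids, pheno$bird_id)]
}

#' SNP-based heritability of a trait
#'
#' Fits the heritability model with `K` = GRM and fixed covariates intercept
#' plus the top `n_pcs` genotype principal components (population-structure
#' adjustment). The variance ratio is reported as h2 with its
#' likelihood-ratio p-value.
#'
#' @param pheno data.frame with `bird_id`, `value` (see [read_phenotypes()]).
#' @param grm a `relationship_matrix` of kind GRM.
#' @param n_pcs number of genotype PCs used as covariates (default 5).
#' @param Keig optional precomputed `eigen(grm)`.
#' @return A `varcomp_est` (ratio = h2).
#' @export
estimate_h2 <- function(pheno, grm, n_pcs = 5, Keig = NULL) {
  y <- align_pheno(pheno, grm$ids)
  X <- matrix(1, length(y), 1)
  if (n_pcs > 0)
    X <- cbind(X, genotype_pca(grm, k = n_pcs)$coordinates)
  reml_single_component(y, grm, X = X, Keig = Keig)
}

#' Microbiability of a trait at one body site
#'
#' Fits the microbiability model with `K` = MRM and fixed covariates
#' intercept + genotype PCs + PCs of trait-significant SNPs (the
#' host-genetics adjustment), reporting the variance ratio as m2.
#'
#' @param pheno data.frame with `bird_id`, `value`.
#' @param mrm a `relationship_matrix` of kind MRM.
#' @param genetic_pcs,snp_pcs covariate matrices with bird IDs as rownames
#'   (either may be `NULL` or have zero columns).
#' @return A `varcomp_est` (ratio = m2) with the site attached.
#' @export
estimate_m2 <- function(pheno, mrm, genetic_pcs = NULL, snp_pcs = NULL) {
  y <- align_pheno(pheno, mrm$ids)
  X <- matrix(1, length(y), 1)
  for (blk in list(genetic_pcs, snp_pcs)) {
    if (!is.null(blk) && ncol(blk) > 0) {
      if (is.null(rownames(blk))) stop_mb("covariate blocks need bird IDs as rownames")
      miss <- setdiff(mrm$ids, rownames(blk))
      if (length(miss)) stop_mb("covariates missing for: %s", paste(miss, collapse = ", "))
      X <- cbind(X, blk[match(mrm$ids, rownames(blk)), , drop = FALSE])
    }
  }
  out <- reml_single_component(y, mrm, X = X)
  out$site <- mrm$site
  out
}

#' Linear mixed-model association scan (single-lambda approximation)
#'
#' EMMAX-style GWAS: the GRM is eigendecomposed once and the variance ratio
#' is estimated once under the covariates-only null model; each SNP is then
#' tested by generalized least squares at that fixed ratio, with a Wald
#' t-test on its effect. This single-lambda scheme is a standard, documented
#' approximation to per-SNP ratio re-optimization. SNPs whose dosage is
#' collinear with the covariates (including monomorphic SNPs) are skipped
#' and flagged. The genomic-control inflation factor `lambda_gc` (median
#' association chi-square over its null expectation) is reported.
#'
#' @param pheno data.frame with `bird_id`, `value`.
#' @param g a [genotype_matrix()] (imputed).
#' @param grm the GRM for the same cohort.
#' @param covariates optional covariate matrix with bird IDs as rownames.
#' @return List: `results` (data.frame snp_id, chrom, pos, beta, se, p,
#'   skipped), `lambda_gc`, `lambda_reml`.
#' @export
lmm_gwas_scan <- function(pheno, g, grm, covariates = NULL) {
  ids <- grm$ids
  if (!all(ids %in% rownames(g$calls)))
    stop_mb("GRM and genotype matrix cover different individuals")
  y <- align_pheno(pheno, ids)
  X <- matrix(1, length(y), 1)
  if (!is.null(covariates) && ncol(covariates) > 0)
    X <- cbind(X, covariates[match(ids, rownames(covariates)), , drop = FALSE])
  e <- eigen(grm$mat, symmetric = TRUE)
  null_fit <- reml_single_component(y, grm, X = X, Keig = e)
  w <- null_fit$lambda * pmax(e$values, 0) + 1
  sw <- sqrt(w)
  yt <- crossprod(e$vectors, y)[, 1] / sw
  Xt <- crossprod(e$vectors, X) / sw
  Gt <- crossprod(e$vectors, g$calls[ids, , drop = FALSE]) / sw
  q0 <- qr(Xt)
  yr <- qr.resid(q0, yt)
  Gr <- qr.resid(q0, Gt)
  den <- colSums(Gr^2)
  num <- colSums(Gr * yr)
  dfree <- length(y) - ncol(X) - 1
  skipped <- den < 1e-10 * max(1, max(den))
  beta <- se <- pval <- rep(NA_real_, ncol(Gr))
  beta[!skipped] <- num[!skipped] / den[!skipped]
  rss <- pmax(sum(yr^2) - num[!skipped]^2 / den[!skipped], 0)
  se[!skipped] <- sqrt(rss / dfree / den[!skipped])
  tt <- beta[!skipped] / se[!skipped]
  pval[!skipped] <- 2 * stats::pt(-abs(tt), df = dfree)
  chisq <- stats::qchisq(pval[!skipped], df = 1, lower.tail = FALSE)
  lambda_gc <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  list(results = data.frame(snp_id = g$map$snp_id, chrom = g$map$chrom,
                            pos = g$map$pos, beta = beta, se = se, p = pval,
                            skipped = skipped, stringsAsFactors = FALSE),
       lambda_gc = lambda_gc, lambda_reml = null_fit$lambda)
}

#' Principal components of trait-significant SNPs
#'
#' Selects SNPs with association `p < p_threshold`, centers and scales their
#' dosages, and returns the top `k` principal-component scores for use as
#' host-genetics covariates in the microbiability model. With no SNP below
#' the threshold an empty (zero-column) design is returned with a warning.
#'
#' @param gwas result of [lmm_gwas_scan()].
#' @param g the [genotype_matrix()] scanned.
#' @param p_threshold genome-wide significance threshold (default 1e-6).
#' @param k number of PCs (default 2).
#' @return Numeric matrix (n x <= k) with bird IDs as rownames.
#' @export
significant_snp_pcs <- function(gwas, g, p_threshold = 1e-6, k = 2) {
  hits <- which(!gwas$results$skipped & gwas$results$p < p_threshold)
  n <- nrow(g$calls)
  if (!length(hits)) {
    warn_mb("no SNP passes p < %g; returning empty covariate block", p_threshold)
    return(matrix(0, n, 0, dimnames = list(rownames(g$calls), NULL)))
  }
  sub <- g$calls[, hits, drop = FALSE]
  sub <- scale(sub)
  sub[, !is.finite(colSums(sub))] <- 0
  k <- min(k, length(hits), n - 1)
  pc <- stats::prcomp(sub, center = FALSE, scale. = FALSE)
  out <- pc$x[, seq_len(k), drop = FALSE]
  rownames(out) <- rownames(g$calls)
  colnames(out) <- paste0("snpPC", seq_len(k))
  out
}
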
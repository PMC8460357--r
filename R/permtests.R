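#' @title Permutation and rank statistics
#' @description ANOSIM, Mantel, Wilcoxon rank-sum, correlation tests and
#'   Benjamini-Hochberg adjustment, with add-one permutation p-values (a
#'   permutation p can never be exactly 0) and explicit seeds.
#' @name permtests
NULL

perm_result <- function(statistic, p_value, method, n_perm, seed, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   n_perm = n_perm, seed = seed), extra),
            class = "mb_perm_test")
}

#' @export
print.mb_perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s permutations, seed %s)\n",
              x$method, x$statistic, x$p_value,
              format(x$n_perm, big.mark = ","), x$seed))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of community differences between groups on a
#' distance matrix: `R = (mean between-group rank - mean within-group rank) /
#' (n(n-1)/4)`, with distances mid-ranked under ties, so `R` is in
#' `[-1, 1]` and invariant to monotone transforms of the distances.
#' The p-value is the upper tail over label permutations with add-one
#' correction.
#'
#' @param d a `dist` or square distance matrix.
#' @param groups group label per sample (at least 2 groups of at least 2).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return An `mb_perm_test` (statistic = R).
#' @export
anosim <- function(d, groups, n_perm = 10000, seed = 1) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop_mb("groups must have one label per sample")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop_mb("need >= 2 groups with >= 2 samples each (sizes: %s)",
            paste(sizes, collapse = ", "))
  dv <- lower_tri_vec(dm)
  if (length(unique(dv)) == 1)
    stop_mb("all distances tie; ANOSIM R is undefined")
  rk <- rank(dv)                     # mid-ranks under ties
  Rk <- matrix(0, n, n)
  Rk[lower.tri(Rk)] <- rk
  Rk <- Rk + t(Rk)
  M <- n * (n - 1) / 2
  denom <- n * (n - 1) / 4
  n_within <- sum(sizes * (sizes - 1) / 2)
  n_between <- M - n_within
  stat_of <- function(lab) {
    sw <- 0
    for (gname in names(sizes)) {
      idx <- which(lab == gname)
      sw <- sw + sum(Rk[idx, idx]) / 2
    }
    mw <- sw / n_within
    mb <- (sum(rk) - sw) / n_between
    (mb - mw) / denom
  }
  obs <- stat_of(groups)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm),
                                        function(i) stat_of(sample(groups)), 0))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  perm_result(obs, p, "ANOSIM", n_perm, seed, list(groups = sizes))
}

#' Mantel test between two distance (or relationship) matrices
#'
#' Correlates the `n(n-1)/2` lower-triangle entries of two matrices over the
#' same samples; significance by simultaneously permuting rows and columns
#' of the second matrix. Two-sided: the p-value counts permuted `|r|` at
#' least as large as observed (the convention needed to report signed
#' correlations with significance).
#'
#' @param d1,d2 `dist` objects or square matrices over the same sample set
#'   and order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm,seed permutations and seed.
#' @return An `mb_perm_test` (statistic = r).
#' @export
mantel <- function(d1, d2, method = c("pearson", "spearman"),
                   n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  m1 <- as_dist_matrix(d1); m2 <- as_dist_matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop_mb("matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop_mb("matrices are over different sample orders")
  v1 <- lower_tri_vec(m1); v2 <- lower_tri_vec(m2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_mb("constant matrix: correlation undefined")
  if (method == "spearman") { v1 <- rank(v1) }   # rank m1 once; m2 re-ranked per perm
  r_of <- function(m) {
    v <- lower_tri_vec(m)
    if (method == "spearman") v <- rank(v)
    stats::cor(v1, v)
  }
  obs <- r_of(m2)
  n <- nrow(m2)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    r_of(m2[p, p])
  }, 0))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  perm_result(obs, p, paste0("Mantel (", method, ")"), n_perm, seed)
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p when both groups have at most 25 observations and no
#' ties; otherwise the normal approximation with tie and continuity
#' correction. The mode actually used is recorded.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`, `mode`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop_mb("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    warn_mb("all values identical across groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                mode = "degenerate"))
  }
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mode = if (exact) "exact" else "normal_approx")
}

#' Correlation test (Pearson t-test or Spearman Z-test)
#'
#' Pearson significance uses the t distribution on `n - 2` df. Spearman
#' significance uses the large-sample Z-test on the Fisher transform of
#' `r_s` with the Fieller-corrected variance `1.06 / (n - 3)`; ties are
#' mid-ranked.
#'
#' @param x,y numeric vectors, `n >= 4`, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p_value`, `method`, `n`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  if (n != length(y) || n < 4) stop_mb("need equal-length x, y with n >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_mb("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_mb("zero variance in x or y")
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value,
         method = "pearson_t", n = n)
  } else {
    r <- stats::cor(rank(x), rank(y))
    if (abs(r) >= 1) {
      p <- 0
    } else {
      z <- atanh(r) / sqrt(1.06 / (n - 3))
      p <- 2 * stats::pnorm(-abs(z))
    }
    list(r = r, p_value = p, method = "spearman_z", n = n)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (monotone, capped at 1, stable under input
#' reordering). Input outside `[0, 1]` is an error.
#'
#' @param p_values numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop_mb("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided permutation test for a difference in means
#'
#' Statistic `|mean(x) - mean(y)|`; p by label shuffling with add-one
#' correction.
#'
#' @param x,y numeric vectors.
#' @param n_perm,seed permutations (a warning below 100) and seed.
#' @return An `mb_perm_test`.
#' @export
permutation_mean_test <- function(x, y, n_perm = 10000, seed = 1) {
  if (!length(x) || !length(y)) stop_mb("both groups must be nonempty")
  if (n_perm < 100) warn_mb("n_perm < 100 gives a very coarse p-value")
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  tot <- sum(pool); n <- length(pool)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sx <- sum(pool[sample.int(n, nx)])
    abs(sx / nx - (tot - sx) / (n - nx))
  }, 0))
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  perm_result(obs, p, "permutation mean test", n_perm, seed)
}
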
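#' Prevalence filter within each site
#'
#' Retains OTUs present (count > 0) in at least `min_fraction` of the
#' samples of at least one site (the per-site sets are unioned), the
#' analysis convention for dropping rarely observed taxa before diversity
#' and association work.
#'
#' @param otu an [mb_otu_table()].
#' @param min_fraction inclusive prevalence threshold in `(0, 1]`
#'   (default 0.20).
#' @return A filtered [mb_otu_table()] with attribute `"prevalence"` holding
#'   retained/dropped counts.
#' @export
prevalence_filter <- function(otu, min_fraction = 0.20) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop_mb("min_fraction must be in (0, 1]")
  keep <- rep(FALSE, ncol(otu$counts))
  for (s in unique(otu$meta$site)) {
    idx <- otu$meta$site == s
    prev <- colMeans(otu$counts[idx, , drop = FALSE] > 0)
    keep <- keep | (prev >= min_fraction)
  }
  if (!any(keep)) stop_mb("no OTU reaches prevalence %.2f in any site", min_fraction)
  out <- mb_otu_table(otu$counts[, keep, drop = FALSE], otu$meta)
  attr(out, "prevalence") <- c(retained = sum(keep), dropped = sum(!keep))
  out
}

#' Per-OTU prevalence at one site
#' @param otu an [mb_otu_table()].
#' @param site site label.
#' @return Named fraction-of-samples-present vector.
#' @export
prevalence <- function(otu, site) {
  sub <- site_subset(otu, site)
  colMeans(sub$counts > 0)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (`"min"` resolves to the smallest sample total, the usual normalization
#' to the sample with the fewest sequences). Deterministic given `seed`.
#'
#' @param otu an [mb_otu_table()].
#' @param depth integer target depth or `"min"`.
#' @param seed RNG seed.
#' @return A rarefied [mb_otu_table()]; every sample total equals `depth`.
#' @export
rarefy <- function(otu, depth = "min", seed = 1) {
  totals <- rowSums(otu$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  low <- totals < depth
  if (any(low))
    stop_mb("samples below rarefaction depth %d: %s", depth,
            paste(rownames(otu$counts)[low], collapse = ", "))
  # rrarefy warns when a sample's smallest nonzero count is tiny; harmless here
  cnt <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(otu$counts, depth)))
  out <- mb_otu_table(cnt, otu$meta)
  attr(out, "rarefaction") <- list(depth = depth, seed = seed)
  out
}

#' Alpha-diversity indices per sample
#'
#' Computed on (integer, typically rarefied) counts: observed OTUs, the
#' bias-corrected Chao1 estimator `S_obs + F1(F1-1)/(2(F2+1))`, ACE with
#' rare-taxon threshold 10, Shannon entropy in log base 2 (the common
#' amplicon-toolchain convention; `base` switches to natural log), the
#' Gini-Simpson index `1 - sum(p^2)`, and Good's coverage `1 - F1/N`.
#'
#' @param otu an [mb_otu_table()] with integer counts.
#' @param base logarithm base for Shannon entropy.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(otu, base = 2) {
  cnt <- otu$counts
  if (any(cnt != floor(cnt))) stop_mb("alpha diversity needs integer counts")
  zero <- rowSums(cnt) == 0
  if (any(zero))
    stop_mb("all-zero sample(s): %s", paste(rownames(cnt)[zero], collapse = ", "))
  est <- t(vegan::estimateR(cnt))   # S.obs, S.chao1, S.ACE (+SEs)
  f1 <- rowSums(cnt == 1)
  data.frame(
    sample_id = rownames(cnt),
    observed_otus = as.integer(est[, "S.obs"]),
    chao1 = unname(est[, "S.chao1"]),
    ace = unname(est[, "S.ACE"]),
    shannon = unname(vegan::diversity(cnt, index = "shannon", base = base)),
    simpson = unname(vegan::diversity(cnt, index = "simpson")),
    goods_coverage = unname(1 - f1 / rowSums(cnt)),
    stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x_k - y_k| / sum(x_k + y_k)` on (rarefied) counts.
#'
#' @param otu an [mb_otu_table()] with at least two samples.
#' @return A `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(otu) {
  if (nrow(otu$counts) < 2) stop_mb("need at least 2 samples")
  zero <- rowSums(otu$counts) == 0
  if (any(zero))
    stop_mb("all-zero sample(s): %s",
            paste(rownames(otu$counts)[zero], collapse = ", "))
  d <- vegan::vegdist(otu$counts, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' UniFrac distances between samples
#'
#' Phylogeny-aware beta diversity on a rooted tree whose leaves cover every
#' OTU in the table. Unweighted UniFrac is the fraction of branch length
#' unique to one of the two communities among branch length covered by
#' either. Weighted UniFrac is the normalized variant,
#' `sum(b |pA - pB|) / sum(b (pA + pB))` over branches with relative
#' abundances `p`, so both metrics live in `[0, 1]`.
#'
#' @param otu an [mb_otu_table()].
#' @param tree an [ape::phylo] (see [read_tree()]).
#' @param weighted logical.
#' @return A `dist` object with a `metric` attribute.
#' @export
unifrac <- function(otu, tree, weighted = FALSE) {
  miss <- setdiff(colnames(otu$counts), tree$tip.label)
  if (length(miss))
    stop_mb("OTUs missing from tree: %s", paste(miss, collapse = ", "))
  if (length(tree$tip.label) > ncol(otu$counts))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, colnames(otu$counts)))
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  b <- tree$edge.length
  # leaf x edge descendant-indicator via postorder accumulation
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(0, n_tip, nrow(edge))
  node_leaves <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) node_leaves[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    child <- po$edge[k, 2]; parent <- po$edge[k, 1]
    node_leaves[[parent]] <- c(node_leaves[[parent]], node_leaves[[child]])
  }
  for (k in seq_len(nrow(edge)))
    desc[node_leaves[[edge[k, 2]]], k] <- 1
  P <- otu$counts[, tree$tip.label, drop = FALSE] / rowSums(otu$counts)
  E <- P %*% desc                              # sample x edge branch abundance
  S <- nrow(E)
  D <- matrix(0, S, S, dimnames = list(rownames(P), rownames(P)))
  if (weighted) {
    for (i in seq_len(S - 1)) {
      dif <- abs(sweep(E[(i + 1):S, , drop = FALSE], 2, E[i, ])) %*% b
      tot <- sweep(E[(i + 1):S, , drop = FALSE], 2, E[i, ], "+") %*% b
      D[(i + 1):S, i] <- D[i, (i + 1):S] <- ifelse(tot > 0, dif / tot, 0)
    }
  } else {
    pres <- (E > 0) + 0
    both <- pres %*% (t(pres) * b)               # shared branch length
    tot <- as.numeric(pres %*% b)
    either <- outer(tot, tot, "+") - both
    uniq <- either - both
    D <- ifelse(either > 0, uniq / either, 0)
    dimnames(D) <- list(rownames(P), rownames(P))
    diag(D) <- 0
  }
  d <- stats::as.dist(D)
  attr(d, "metric") <- if (weighted) "weighted_unifrac_normalized" else "unweighted_unifrac"
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: double-center `-D^2/2`, eigendecompose, keep the
#' top `k` nonnegative eigenvalues. Explained-variance fractions are each
#' positive eigenvalue over the sum of positive eigenvalues; negative
#' eigenvalues (from non-Euclidean metrics) are reported but unused.
#'
#' @param d a `dist` or square distance matrix.
#' @param k number of axes (`1 <= k <= n - 1`).
#' @return List with `coordinates` (n x k), `explained` (length k),
#'   `eigenvalues` (all n).
#' @export
pcoa <- function(d, k = 2) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (k <= 0 || k > n - 1) stop_mb("k must be in 1..%d", n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[eig > 0])
  if (pos <= 0) stop_mb("degenerate distance matrix: no positive eigenvalues")
  coords <- fit$points
  if (ncol(coords) < k)
    stop_mb("only %d positive axes available, requested %d", ncol(coords), k)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       explained = pmax(eig[seq_len(k)], 0) / pos,
       eigenvalues = eig)
}
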
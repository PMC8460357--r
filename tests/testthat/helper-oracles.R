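# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately implemented differently from the package path
# it checks (dense algebra instead of spectral forms, brute-force loops
# instead of vectorized matrix identities).

# --- dense-matrix restricted log-likelihood (no eigendecomposition) -------
dense_reml_ll <- function(lambda, y, K, X) {
  n <- length(y); p <- ncol(X)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  -0.5 * ((n - p) * (log(2 * pi) + 1) + (n - p) * log(rss / (n - p)) +
          as.numeric(determinant(V)$modulus) +
          as.numeric(determinant(XtViX)$modulus))
}

# --- 401-point grid + golden-section search for the REML variance ratio ---
grid_reml_ratio <- function(y, K, X = matrix(1, length(y), 1)) {
  grid <- 10^seq(-4, 4, length.out = 401)
  ll <- vapply(grid, function(l) dense_reml_ll(l, y, K, X), 0)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- dense_reml_ll(exp(c1), y, K, X); fd <- dense_reml_ll(exp(d1), y, K, X)
  for (it in 1:60) {
    if (fc > fd) { b <- d1; d1 <- c1; fd <- fc
                   c1 <- b - gr * (b - a); fc <- dense_reml_ll(exp(c1), y, K, X)
    } else { a <- c1; c1 <- d1; fc <- fd
             d1 <- a + gr * (b - a); fd <- dense_reml_ll(exp(d1), y, K, X) }
  }
  lam <- exp((a + b) / 2)
  if (dense_reml_ll(1e-10, y, K, X) >= dense_reml_ll(lam, y, K, X)) lam <- 0
  lam / (1 + lam)
}

# --- brute-force GRM (explicit double loop over individuals and SNPs) -----
brute_grm <- function(calls) {
  n <- nrow(calls); m <- ncol(calls)
  f <- colMeans(calls) / 2
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (a in 1:m)
      s <- s + (calls[i, a] - 2 * f[a]) * (calls[j, a] - 2 * f[a]) /
               (2 * f[a] * (1 - f[a]))
    out[i, j] <- s / m
  }
  out
}

# --- edge-by-edge UniFrac tally on an ape tree ----------------------------
brute_unifrac_pair <- function(tree, x1, x2, weighted) {
  # x1, x2: named counts over tips
  tips <- tree$tip.label
  p1 <- x1[tips] / sum(x1); p2 <- x2[tips] / sum(x2)
  num <- den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    desc <- tips_under(tree, tree$edge[k, 2])
    a <- sum(p1[desc]); b <- sum(p2[desc])
    bl <- tree$edge.length[k]
    if (weighted) {
      num <- num + bl * abs(a - b)
      den <- den + bl * (a + b)
    } else {
      if (a > 0 || b > 0) {
        den <- den + bl
        if (xor(a > 0, b > 0)) num <- num + bl
      }
    }
  }
  num / den
}

tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

# --- small builders -------------------------------------------------------
toy_otu <- function(counts, sites = NULL, birds = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  n <- nrow(counts)
  meta <- data.frame(sample_id = rownames(counts),
                     bird_id = birds %||% paste0("B", seq_len(n)),
                     site = sites %||% rep("crop", n),
                     stringsAsFactors = FALSE)
  mb_otu_table(counts, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

euclid_dist <- function(pts) as.matrix(stats::dist(pts))

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
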
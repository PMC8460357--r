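# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mb <- function(...) stop(sprintf(...), call. = FALSE)

warn_mb <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_mb("`%s` must be a single number in [%g, %g]", name, lo, hi)
  invisible(x)
}

# population (divisor-n) variance / sd
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd  <- function(x) sqrt(pop_var(x))

# scale a vector to an exact population-variance target; zero-variance input
# stays at zero so degenerate components contribute nothing
scale_to_share <- function(x, share) {
  s <- pop_sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s * sqrt(share)
}

# derive a distinct 32-bit sub-seed from a master seed and a stage label
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# read a tab-separated file with '#'-comment lines ignored
read_tsv_mb <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_mb <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               row_label),
               as.data.frame(x, check.names = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# lower-triangle vector of a square matrix (column-major, excludes diagonal)
lower_tri_vec <- function(m) m[lower.tri(m)]

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
}
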
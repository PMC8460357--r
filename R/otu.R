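#' OTU count table with sample metadata
#'
#' Samples-by-OTUs count matrix plus the per-sample metadata needed by the
#' variance-partitioning analysis: which bird a sample came from and which
#' body site (crop, gizzard, small_intestine, vagina, uterus, isthmus in the
#' laying-hen design, but any site labels are accepted). A bird may appear at
#' most once per site.
#'
#' @param counts nonnegative integer matrix, samples x OTUs, with sample IDs
#'   as rownames and OTU IDs as colnames.
#' @param meta data.frame with columns `sample_id`, `bird_id`, `site`.
#' @return An object of class `mb_otu_table` with elements `counts` and
#'   `meta` (rows of `meta` aligned to rows of `counts`).
#' @export
mb_otu_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_mb("counts must have sample IDs as rownames and OTU IDs as colnames")
  if (any(counts < 0) || any(counts != floor(counts))) {
    bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)[1, ]
    stop_mb("counts must be nonnegative integers (sample '%s', OTU '%s')",
            rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  need <- c("sample_id", "bird_id", "site")
  if (!all(need %in% names(meta)))
    stop_mb("meta must have columns: %s", paste(need, collapse = ", "))
  missing_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing_meta))
    stop_mb("samples absent from metadata: %s", paste(missing_meta, collapse = ", "))
  meta <- meta[match(rownames(counts), meta$sample_id), need]
  dup <- duplicated(meta[, c("bird_id", "site")])
  if (any(dup))
    stop_mb("bird appears more than once per site: %s",
            paste(sprintf("(%s, %s)", meta$bird_id[dup], meta$site[dup]),
                  collapse = ", "))
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "mb_otu_table")
}

#' @export
print.mb_otu_table <- function(x, ...) {
  cat(sprintf("mb_otu_table: %d samples x %d OTUs; sites: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$meta$site)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mb_otu_table <- function(x) dim(x$counts)

#' Subset an OTU table to the samples of one body site
#'
#' @param otu an [mb_otu_table()].
#' @param site site label.
#' @return An [mb_otu_table()] with rows ordered by `bird_id`.
#' @export
site_subset <- function(otu, site) {
  idx <- which(otu$meta$site == site)
  if (!length(idx)) stop_mb("site '%s' not present (have: %s)", site,
                            paste(unique(otu$meta$site), collapse = ", "))
  idx <- idx[order(otu$meta$bird_id[idx])]
  mb_otu_table(otu$counts[idx, , drop = FALSE], otu$meta[idx, ])
}

#' Read an OTU count table and its sample metadata
#'
#' @param counts_path TSV whose header row holds OTU IDs and whose first
#'   column holds sample IDs.
#' @param meta_path TSV with columns `sample_id`, `bird_id`, `site`.
#' @return An [mb_otu_table()].
#' @export
read_otu_table <- function(counts_path, meta_path) {
  raw <- read_tsv_mb(counts_path)
  if (ncol(raw) < 2) stop_mb("%s: expected sample-ID column plus OTU columns", counts_path)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- as.character(raw[[1]])
  if (any(is.na(counts)))
    stop_mb("%s: non-numeric or missing count (first at sample '%s')",
            counts_path,
            rownames(counts)[which(rowSums(is.na(counts)) > 0)[1]])
  meta <- read_tsv_mb(meta_path)
  meta$sample_id <- as.character(meta$sample_id)
  meta$bird_id <- as.character(meta$bird_id)
  mb_otu_table(counts, meta)
}

#' Write an OTU table (and its metadata) as TSV
#' @param otu an [mb_otu_table()].
#' @param counts_path,meta_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_otu_table <- function(otu, counts_path, meta_path) {
  write_tsv_mb(otu$counts, counts_path, row_label = "sample_id")
  write_tsv_mb(otu$meta, meta_path)
  invisible(counts_path)
}

#' Read a rooted phylogenetic tree in newick format
#'
#' Missing branch lengths are set to 0 with a warning; duplicate leaf names
#' are an error because UniFrac needs a unique leaf per OTU.
#'
#' @param path newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_mb("newick parse error in %s: %s",
                                               path, conditionMessage(e)))
  if (is.null(tree)) stop_mb("newick parse error in %s", path)
  if (anyDuplicated(tree$tip.label))
    stop_mb("duplicate leaf names: %s",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warn_mb("tree in %s has no branch lengths; using 0", path)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warn_mb("tree in %s has missing branch lengths; using 0", path)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop_mb("negative branch lengths in %s", path)
  tree
}

#' Read a phenotype table
#'
#' @param path TSV with columns `bird_id` and `value` (additional columns are
#'   kept as covariates). Rows with missing phenotype are dropped with a
#'   warning.
#' @return data.frame with one row per bird.
#' @export
read_phenotypes <- function(path) {
  ph <- read_tsv_mb(path)
  if (!all(c("bird_id", "value") %in% names(ph)))
    stop_mb("%s: need columns bird_id and value", path)
  ph$bird_id <- as.character(ph$bird_id)
  val <- suppressWarnings(as.numeric(ph$value))
  bad <- which(!is.na(ph$value) & ph$value != "NA" & is.na(val))
  if (length(bad))
    stop_mb("%s: non-numeric phenotype at row %d ('%s')", path, bad[1], ph$value[bad[1]])
  drop <- is.na(val)
  if (any(drop)) {
    warn_mb("%s: dropped %d row(s) with missing phenotype", path, sum(drop))
    ph <- ph[!drop, , drop = FALSE]
    val <- val[!drop]
  }
  if (anyDuplicated(ph$bird_id))
    stop_mb("%s: duplicated bird_id: %s", path,
            paste(unique(ph$bird_id[duplicated(ph$bird_id)]), collapse = ", "))
  if (!all(is.finite(val))) stop_mb("%s: non-finite phenotype values", path)
  ph$value <- val
  rownames(ph) <- NULL
  ph
}
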
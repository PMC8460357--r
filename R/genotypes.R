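#' Genotype matrix of reference-allele counts
#'
#' Container for biallelic SNP genotypes coded as the number of REFERENCE
#' alleles carried by each individual (0, 1 or 2, `NA` = missing). Note that
#' this is the coding used throughout the variance-partitioning models here
#' (`r_ia`, the number of reference alleles), and is the opposite of the
#' ALT-allele dosage most VCF tooling reports: a `0/0` genotype is dosage 2.
#'
#' @param calls numeric matrix, individuals x SNPs, entries in `{0, 1, 2}` or
#'   `NA`; after mean-imputation (see [filter_variants()]) entries may be
#'   fractional.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per column of `calls`.
#' @param imputed logical; `TRUE` once missing calls have been mean-imputed.
#'
#' @return An object of class `genotype_matrix` with elements `calls`, `map`
#'   and `imputed`.
#' @export
genotype_matrix <- function(calls, map, imputed = FALSE) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop_mb("`calls` must have individual IDs as rownames")
  if (anyDuplicated(rownames(calls)))
    stop_mb("duplicate individual IDs: %s",
            paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (nrow(map) != ncol(calls))
    stop_mb("map has %d rows but calls has %d SNP columns", nrow(map), ncol(calls))
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map)))
    stop_mb("map must have columns: %s", paste(need, collapse = ", "))
  if (!imputed) {
    bad <- calls[!is.na(calls) & !(calls %in% c(0, 1, 2))]
    if (length(bad))
      stop_mb("non-missing calls must be 0, 1 or 2 (found %s)", bad[1])
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop_mb("positions not strictly increasing on chromosome %s", ch)
  }
  colnames(calls) <- map$snp_id
  structure(list(calls = calls, map = map, imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s, %s)\n",
              nrow(x$calls), ncol(x$calls),
              if (x$imputed) "mean-imputed" else
                sprintf("%.2f%% missing", 100 * mean(is.na(x$calls))),
              "reference-allele coded"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read a VCF into a reference-allele dosage matrix
#'
#' Keeps only biallelic SNP records (single-base REF and ALT). Genotypes are
#' converted to reference-allele counts: `0/0` -> 2, `0/1` -> 1, `1/1` -> 0,
#' `./.` -> `NA`. Phased separators are accepted. Sample order follows the
#' VCF header.
#'
#' @param path path to a VCF 4.x file (may contain multiallelic records,
#'   which are dropped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_mb("VCF not found: %s", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop_mb("VCF parse error in %s: %s",
                                              path, conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)  # stays a matrix even for 1 record
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  if (!any(keep))
    stop_mb("no biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- function(s) {
    out <- rep(NA_real_, length(s))
    out[s %in% "0/0"] <- 2
    out[s %in% c("0/1", "1/0")] <- 1
    out[s %in% "1/1"] <- 0
    out
  }
  coded <- matrix(code(as.vector(gt)), nrow = nrow(gt))  # SNPs x samples
  calls <- t(coded)                                      # samples x SNPs
  rownames(calls) <- colnames(gt)
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids)) ids <- paste0(fix$CHROM, "_", fix$POS)
  ids <- make.unique(ids, sep = "_dup")
  map <- data.frame(snp_id = ids, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Inverse of [read_vcf()] for unimputed matrices (round-trips calls exactly).
#'
#' @param g a [genotype_matrix()] with calls in `{0, 1, 2, NA}`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  if (g$imputed) stop_mb("cannot write an imputed (fractional-dosage) matrix as VCF")
  gt_of <- c("1/1", "0/1", "0/0")          # dosage 0,1,2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=microbiability",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$calls)), collapse = "\t")),
             con)
  for (j in seq_len(ncol(g$calls))) {
    d <- g$calls[, j]
    gt <- ifelse(is.na(d), "./.", gt_of[d + 1L])
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$snp_id[j],
                       g$map$ref[j], g$map$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test (Wigginton et al. convention, no mid-p): the p-value
#' sums the probabilities of all heterozygote counts, conditional on the
#' observed allele counts, whose probability does not exceed that of the
#' observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_alt + n_het               # minor-allele bookkeeping below
  n_r <- 2 * n_hom_ref + n_het
  rare <- min(n_a, n_r)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)       # feasible het counts, same parity
  # log P(n_het = h | allele counts) up to a constant
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_comm <- (2 * n - rare - h) / 2
    h * log(2) - lfactorial(h) - lfactorial(hom_rare) - lfactorial(hom_comm)
  }, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Apply variant- and sample-level quality control
#'
#' Filter order is fixed: (1) drop individuals whose call rate is <=
#' `sample_call_rate`; (2) drop SNPs whose call rate is <= `snp_call_rate`,
#' whose minor allele frequency is <= `maf_min`, or whose exact
#' Hardy-Weinberg p-value is < `hwe_p_min`. Remaining missing calls are
#' imputed to the SNP's mean reference-allele dosage, so downstream
#' relationship matrices are defined for every individual.
#'
#' Defaults are the conventional resequencing thresholds (call rates >90% /
#' >95%, MAF >1%, HWE p >= 1e-5).
#'
#' @param g a [genotype_matrix()].
#' @param sample_call_rate,snp_call_rate,maf_min minimum retained fractions.
#' @param hwe_p_min minimum exact-HWE p-value.
#' @return A mean-imputed [genotype_matrix()] with a `qc` attribute holding
#'   per-filter removal counts.
#' @export
filter_variants <- function(g, sample_call_rate = 0.9, snp_call_rate = 0.95,
                            maf_min = 0.01, hwe_p_min = 1e-5) {
  assert_fraction(sample_call_rate, "sample_call_rate")
  assert_fraction(snp_call_rate, "snp_call_rate")
  assert_fraction(maf_min, "maf_min")
  assert_fraction(hwe_p_min, "hwe_p_min")
  calls <- g$calls
  ind_cr <- rowMeans(!is.na(calls))
  drop_ind <- ind_cr <= sample_call_rate
  calls <- calls[!drop_ind, , drop = FALSE]
  if (nrow(calls) == 0) stop_mb("all individuals removed by call-rate filter")

  snp_cr <- colMeans(!is.na(calls))
  f <- colMeans(calls, na.rm = TRUE) / 2      # reference-allele frequency
  maf <- pmin(f, 1 - f)
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    x <- calls[, j]
    hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  }, 0)
  fail_cr <- snp_cr <= snp_call_rate
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  counts <- c(individuals = sum(drop_ind), snp_call_rate = sum(fail_cr),
              maf = sum(fail_maf & !fail_cr),
              hwe = sum(fail_hwe & !fail_cr & !fail_maf))
  if (!any(keep))
    stop_mb("all SNPs removed by QC (call rate: %d, MAF: %d, HWE: %d)",
            counts[["snp_call_rate"]], counts[["maf"]], counts[["hwe"]])
  calls <- calls[, keep, drop = FALSE]
  # mean-dosage imputation preserves each SNP's allele frequency
  for (j in which(colSums(is.na(calls)) > 0)) {
    m <- mean(calls[, j], na.rm = TRUE)
    calls[is.na(calls[, j]), j] <- m
  }
  out <- genotype_matrix(calls, g$map[keep, , drop = FALSE], imputed = TRUE)
  attr(out, "qc") <- counts
  out
}

#' Reference-allele frequencies of a genotype matrix
#' @param g a [genotype_matrix()].
#' @return Numeric vector, one frequency per SNP.
#' @export
allele_freq <- function(g) colMeans(g$calls, na.rm = TRUE) / 2
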
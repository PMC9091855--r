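#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic SNP: conditional on the observed
#' number of minor alleles, sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' configuration (the standard GWAS-QC exact test).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygote, heterozygote, other
#'   homozygote); missing genotypes are simply not counted.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_minor <- min(n_a, 2 * n - n_a)
  # heterozygote count must share parity with the minor-allele count
  het <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het | n_minor, n) up to a constant
  n_major <- 2 * n - n_minor
  lp <- lgamma(n + 1) - lgamma((n_minor - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((n_major - het) / 2 + 1) + het * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_ab, het)]
  if (is.na(obs)) stop("inconsistent genotype counts for HWE test")
  sum(p[p <= obs + 1e-12])
}

#' Per-SNP summary statistics used by QC
#'
#' @param g A `GenotypeSet`.
#' @return Data frame with columns `snp_id`, `freq_ref`, `maf`, `missingness`,
#'   `hwe_p`.
#' @export
snp_stats <- function(g) {
  geno <- g$geno
  n <- nrow(geno)
  miss <- colMeans(is.na(geno))
  freq <- colMeans(geno, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- NA_real_
  maf <- pmin(freq, 1 - freq)
  hwe <- vapply(seq_len(ncol(geno)), function(j) {
    cnt <- tabulate(geno[, j] + 1L, nbins = 3L)
    hwe_exact_test(cnt[3], cnt[2], cnt[1])
  }, numeric(1))
  data.frame(snp_id = colnames(geno), freq_ref = freq, maf = maf,
             missingness = miss, hwe_p = hwe, stringsAsFactors = FALSE)
}

#' Genotype and individual quality control
#'
#' Removes individuals below the call-rate threshold first, then (on the
#' surviving individuals) SNPs failing missingness, minor-allele-frequency or
#' Hardy-Weinberg exact-test thresholds. The defaults reproduce a standard
#' SNP-chip QC: SNPs with more than 2% missing data, MAF below 0.01 or HWE
#' exact p below 1e-5 are dropped; individuals must be typed at 95% of SNPs.
#'
#' @param g A `GenotypeSet`.
#' @param max_snp_missing Maximum tolerated per-SNP missingness.
#' @param min_maf Minimum minor allele frequency (SNPs with MAF strictly below
#'   are removed).
#' @param hwe_alpha HWE exact-test significance threshold (p strictly below is
#'   removed).
#' @param min_ind_callrate Minimum per-individual call rate.
#' @return The filtered `GenotypeSet`, with a `qc_report` attribute: a data
#'   frame of removal counts per criterion.
#' @export
qc_filter <- function(g, max_snp_missing = 0.02, min_maf = 0.01,
                      hwe_alpha = 1e-5, min_ind_callrate = 0.95) {
  stopifnot(nrow(g$geno) >= 1, ncol(g$geno) >= 1)
  callrate <- rowMeans(!is.na(g$geno))
  keep_ind <- callrate >= min_ind_callrate
  n_ind_removed <- sum(!keep_ind)
  g2 <- subset_genotypes(g, ids = rownames(g$geno)[keep_ind])
  st <- snp_stats(g2)
  fail_miss <- st$missingness > max_snp_missing
  fail_maf <- is.na(st$maf) | st$maf < min_maf
  fail_hwe <- st$hwe_p < hwe_alpha
  keep_snp <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep_snp)) stop("QC removed every SNP; relax the thresholds")
  out <- subset_genotypes(g2, snps = st$snp_id[keep_snp])
  report <- data.frame(
    criterion = c("individual_callrate", "snp_missingness", "snp_maf",
                  "snp_hwe", "individuals_kept", "snps_kept"),
    threshold = c(min_ind_callrate, max_snp_missing, min_maf, hwe_alpha, NA, NA),
    n_removed = c(n_ind_removed, sum(fail_miss), sum(fail_maf & !fail_miss),
                  sum(fail_hwe & !fail_miss & !fail_maf), NA, NA),
    n_after = c(NA, NA, NA, NA, nrow(out$geno), ncol(out$geno))
  )
  attr(out, "qc_report") <- report
  out
}

#' Restrict phenotype records to the analysed measurement window
#'
#' Keeps only records taken in the stated capture month at or beyond the
#' minimum age; repeated annual measures of an individual are all retained.
#' The defaults restrict to August captures of animals at least 28 months old,
#' which removes most growth-related complications for a late-maturing trait.
#'
#' @param records Data frame of phenotype records with columns `id`, `weight`,
#'   `capture_age` (months), `capture_year`, `capture_month`, `sex`.
#' @param min_age_months Minimum capture age in months (inclusive).
#' @param month Capture month kept (integer, default 8 = August).
#' @return The filtered records.
#' @export
filter_phenotypes <- function(records, min_age_months = 28, month = 8L) {
  stopifnot(all(c("id", "weight", "capture_age", "capture_year",
                  "capture_month") %in% names(records)))
  if (any(records$weight <= 0, na.rm = TRUE)) stop("weights must be positive")
  keep <- records$capture_month == month & records$capture_age >= min_age_months
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no phenotype records pass the age/month filter")
  rownames(out) <- NULL
  out
}

#' Reference-allele frequencies of a GenotypeSet
#'
#' @param g A `GenotypeSet`.
#' @param ids Optional subset of individuals over which to compute frequencies
#'   (e.g. the training population).
#' @return Named numeric vector of reference-allele frequencies per SNP.
#' @export
allele_freq <- function(g, ids = rownames(g$geno)) {
  geno <- g$geno[match(ids, rownames(g$geno)), , drop = FALSE]
  p <- colMeans(geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0.5
  p
}

#' Centered, mean-imputed genotype matrix
#'
#' Missing genotypes are replaced by twice the allele frequency (their mean),
#' and every column is centered by the same quantity, so imputed entries are
#' exactly zero after centering.
#'
#' @param g A `GenotypeSet`.
#' @param ids Individuals (rows) wanted, in order.
#' @param freq Reference-allele frequencies used for imputation and centering
#'   (typically training-population frequencies).
#' @return Dense numeric matrix, `length(ids)` x n_snps.
#' @export
centered_genotypes <- function(g, ids = rownames(g$geno), freq = allele_freq(g, ids)) {
  ri <- match(ids, rownames(g$geno))
  if (anyNA(ri)) stop("individuals not genotyped: ",
                      paste(ids[is.na(ri)][seq_len(min(3, sum(is.na(ri))))], collapse = ", "))
  X <- g$geno[ri, , drop = FALSE]
  storage.mode(X) <- "double"
  mu <- 2 * freq
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- mu[j]
    X[, j] <- xj - mu[j]
  }
  X
}
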
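#' Gene-dropping configuration
#'
#' @param founder_year_cutoff Individuals born before this year are treated
#'   as founders and receive two haplotypes sampled (with replacement) from
#'   the phased pool, regardless of recorded parents. The full-scale study
#'   convention is 1990.
#' @param donor_window Length-2 vector: an individual with a missing recorded
#'   parent receives, in place of that parent's gamete, a haplotype copied
#'   from a random already-simulated individual of the required sex born
#'   between `donor_window[1]` and `donor_window[2]` years before it; the
#'   window is widened symmetrically when empty, with the founder pool as the
#'   final fallback.
#' @param seed Integer seed.
#' @return A `GeneDropConfig` list.
#' @export
gene_drop_config <- function(founder_year_cutoff = 1990,
                             donor_window = c(2, 10), seed = 1) {
  stopifnot(length(donor_window) == 2, donor_window[2] > donor_window[1],
            donor_window[1] >= 0)
  structure(list(founder_year_cutoff = as.integer(founder_year_cutoff),
                 donor_window = as.integer(donor_window),
                 seed = as.integer(seed)),
            class = "GeneDropConfig")
}

# Candidate donor indices (into birth-ordered pedigree rows) for each
# individual's missing parent slots; computed once per pedigree + config.
# A missing sire needs a male donor, a missing dam a female donor, born
# within the window before the focal individual's birth year; widening is
# +/- 1 year at both ends until a candidate exists or the pedigree span is
# exhausted (then the empty vector signals the pool fallback).
donor_candidates <- function(ped, cfg) {
  n <- nrow(ped)
  by <- ped$birth_year
  span <- diff(range(by))
  founder <- by < cfg$founder_year_cutoff
  find <- function(i, need_sex) {
    lo <- cfg$donor_window[1]; hi <- cfg$donor_window[2]
    repeat {
      cand <- which(ped$sex == need_sex &
                      by >= by[i] - hi & by <= by[i] - lo & seq_len(n) != i)
      # donors must already be simulated: born strictly before the focal
      cand <- cand[by[cand] < by[i]]
      if (length(cand) > 0) return(cand)
      if (lo == 0 && hi >= span) return(integer(0))
      lo <- max(lo - 1L, 0L); hi <- hi + 1L
    }
  }
  ds <- dd <- rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    if (founder[i]) next
    if (is.na(ped$sire[i])) ds[[i]] <- find(i, "M")
    if (is.na(ped$dam[i])) dd[[i]] <- find(i, "F")
  }
  list(sire = ds, dam = dd)
}

#' Gene-drop phased haplotypes through a pedigree
#'
#' Founders (born before the cutoff) draw two haplotypes from the phased
#' pool with replacement; every other individual receives one recombinant
#' gamete per recorded parent — a gamete walks along the SNP order copying
#' from one of the parent's two haplotypes and switches template between
#' adjacent SNPs with probability equal to that interval's recombination
#' fraction (0.5 across chromosome boundaries, enforcing independent
#' segregation). Missing parents are replaced by donor haplotypes (see
#' [gene_drop_config()]). The output carries no missing genotypes.
#'
#' @param ped A validated `Pedigree`.
#' @param pool Phased haplotype pool: matrix haplotypes x SNPs of 0/1 alleles
#'   (e.g. from [simulate_founder_haplotypes()] or the phased haplotypes of a
#'   `GenotypeSet`).
#' @param map A `GeneticMap` covering the pool's SNPs in order.
#' @param cfg A [gene_drop_config()].
#' @param seed Seed for this drop (overrides `cfg$seed`).
#' @param donors Precomputed [donor_candidates()] (recomputed if `NULL`);
#'   pass them explicitly when running many drops on one pedigree.
#' @return A `GenotypeSet` of simulated genotypes for every pedigree member.
#' @export
gene_drop <- function(ped, pool, map, cfg = gene_drop_config(),
                      seed = cfg$seed, donors = NULL) {
  if (nrow(pool) == 0) stop("empty founder haplotype pool")
  stopifnot(ncol(pool) == nrow(map))
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  founder <- ped$birth_year < cfg$founder_year_cutoff
  if (!any(founder)) stop("no individuals born before the founder cutoff ",
                          cfg$founder_year_cutoff)
  if (is.null(donors)) donors <- donor_candidates(ped, cfg)
  sire <- match(ped$sire, ped$id); sire[is.na(sire)] <- 0L
  dam <- match(ped$dam, ped$id); dam[is.na(dam)] <- 0L
  # a recorded parent that is itself below a younger individual in the order
  # is guaranteed earlier because parents are born strictly earlier
  set.seed(seed)
  geno_t <- gene_drop_cpp(t(pool), switch_probs(map), sire, dam, founder,
                          donors$sire, donors$dam)
  geno <- t(geno_t)
  dimnames(geno) <- list(ped$id, map$snp_id)
  genotype_set(geno, map = map)
}

#' Gene-dropping drift null for the genomic breeding-value trend
#'
#' For posterior sample s, runs one gene-drop of the pedigree, converts the
#' simulated genotypes to breeding values with that sample's SNP effects
#' (same centering as [predict_gebv()]) and computes the size-weighted cohort
#' trend slope. The resulting null slopes are paired 1:1 with the posterior
#' samples of the real data.
#'
#' @param ped A `Pedigree`.
#' @param pool,map As in [gene_drop()].
#' @param chain A `PosteriorChain`; its sample count fixes the number of
#'   drift simulations.
#' @param cfg A [gene_drop_config()]; per-simulation seeds derive from
#'   `cfg$seed`.
#' @param year_range,min_cohort_size Passed to [cohort_means()].
#' @param ids Individuals entering the trend (default: all pedigree members;
#'   pass the genotyped subset to mirror the real-data analysis).
#' @return Numeric vector of null slopes (kg/yr), one per posterior sample.
#' @export
drift_null_genomic <- function(ped, pool, map, chain, cfg = gene_drop_config(),
                               year_range = NULL, min_cohort_size = 100,
                               ids = ped$id) {
  S <- nrow(chain$beta)
  stopifnot(identical(chain$snp_ids, map$snp_id), ncol(pool) == nrow(map))
  if (nrow(pool) == 0) stop("empty founder haplotype pool")
  ord <- pedigree_order(ped)
  pedo <- ped[ord, , drop = FALSE]
  founder <- pedo$birth_year < cfg$founder_year_cutoff
  if (!any(founder)) stop("no individuals born before the founder cutoff ",
                          cfg$founder_year_cutoff)
  donors <- donor_candidates(pedo, cfg)
  sire <- match(pedo$sire, pedo$id); sire[is.na(sire)] <- 0L
  dam <- match(pedo$dam, pedo$id); dam[is.na(dam)] <- 0L
  pool_t <- t(pool)
  sw <- switch_probs(map)

  # cohort bookkeeping, fixed across simulations
  ri <- match(ids, pedo$id)
  if (anyNA(ri)) stop("ids not in pedigree")
  by <- pedo$birth_year[ri]
  keep <- if (is.null(year_range)) rep(TRUE, length(by)) else
    by >= year_range[1] & by <= year_range[2]
  sizes <- table(by[keep])
  retained <- as.integer(names(sizes)[sizes >= min_cohort_size])
  if (length(retained) < 2) {
    stop("fewer than 2 cohorts of at least ", min_cohort_size, " individuals")
  }
  keep <- keep & by %in% retained
  grp <- factor(by[keep], levels = sort(retained))
  n_coh <- as.integer(table(grp))
  years <- as.integer(levels(grp))
  cols <- ri[keep]

  # the 2*p*beta centering constant is shared by every individual and drops
  # out of the slope, so breeding values are accumulated uncentered here;
  # gene_drop() + predict_gebv() give identical slopes (see tests)
  slopes <- numeric(S)
  for (s in seq_len(S)) {
    set.seed(as.integer((cfg$seed + 1000003 * s) %% .Machine$integer.max))
    geno_t <- gene_drop_cpp(pool_t, sw, sire, dam, founder,
                            donors$sire, donors$dam)
    gebv <- drop(crossprod(geno_t[, cols, drop = FALSE], chain$beta[s, ]))
    means <- rowsum(gebv, grp) / n_coh
    slopes[s] <- weighted_slope(years, as.numeric(means), n_coh)
  }
  slopes
}

#' Midparent breeding-value drift null
#'
#' The classical infinitesimal drift simulation: per posterior sample s,
#' founders (here: individuals with both parents unrecorded) draw breeding
#' values from Normal(0, sigma2_A^(s)); each individual with recorded
#' parents draws from Normal(midparent BV, sigma2_A^(s)/2). An individual
#' with one recorded parent receives a phantom parent drawn from
#' Normal(0, sigma2_A^(s)), so the marginal breeding-value variance stays at
#' sigma2_A. The size-weighted cohort slope of each simulation is the null
#' slope.
#'
#' @param ped A `Pedigree`.
#' @param sigma2A_posterior Posterior samples of the additive genetic
#'   variance (kg^2), one simulation per sample.
#' @param seed Integer seed.
#' @param year_range,min_cohort_size Passed to [cohort_means()].
#' @param ids Individuals entering the trend (default all).
#' @return Numeric vector of null slopes, one per posterior sample.
#' @export
drift_null_pedigree <- function(ped, sigma2A_posterior, seed = 1,
                                year_range = NULL, min_cohort_size = 100,
                                ids = ped$id) {
  if (any(sigma2A_posterior < 0)) stop("negative additive genetic variance")
  ord <- pedigree_order(ped)
  pedo <- ped[ord, , drop = FALSE]
  n <- nrow(pedo)
  sire <- match(pedo$sire, pedo$id); sire[is.na(sire)] <- 0L
  dam <- match(pedo$dam, pedo$id); dam[is.na(dam)] <- 0L
  S <- length(sigma2A_posterior)
  set.seed(seed)
  value <- matrix(0, n, S, dimnames = list(pedo$id, NULL))
  for (s in seq_len(S)) {
    value[, s] <- midparent_drop(sire, dam, sigma2A_posterior[s])
  }
  ebv <- ebv_posterior(value[match(ids, pedo$id), , drop = FALSE],
                       birth_year = ped, provenance = "pedigree")
  cm <- cohort_means(ebv, year_range, min_cohort_size)
  weighted_slope(cm$years, cm$means, cm$sizes)
}

# one midparent breeding-value drop over a topologically ordered pedigree;
# consumes the current RNG stream
midparent_drop <- function(sire, dam, s2) {
  n <- length(sire)
  bv <- numeric(n)
  if (s2 <= 0) return(bv)
  z <- stats::rnorm(n)            # segregation / founder deviates
  zs <- stats::rnorm(n)           # phantom sire
  zd <- stats::rnorm(n)           # phantom dam
  for (i in seq_len(n)) {
    if (sire[i] == 0 && dam[i] == 0) {
      bv[i] <- z[i] * sqrt(s2)    # founder
    } else {
      ps <- if (sire[i] > 0) bv[sire[i]] else zs[i] * sqrt(s2)
      pd <- if (dam[i] > 0) bv[dam[i]] else zd[i] * sqrt(s2)
      bv[i] <- (ps + pd) / 2 + z[i] * sqrt(s2 / 2)
    }
  }
  bv
}

# single named-vector drop for tests/diagnostics
drift_bv_once <- function(ped, s2, seed = 1) {
  ord <- pedigree_order(ped)
  pedo <- ped[ord, , drop = FALSE]
  sire <- match(pedo$sire, pedo$id); sire[is.na(sire)] <- 0L
  dam <- match(pedo$dam, pedo$id); dam[is.na(dam)] <- 0L
  set.seed(seed)
  stats::setNames(midparent_drop(sire, dam, s2), pedo$id)
}

#' Drift-adjusted probability of the observed trend
#'
#' Pairs each posterior sample's real slope with the drift simulation run
#' under that same sample, forms the differences, and reports
#' `p_drift` = the proportion of pairs in which the null slope strictly
#' exceeds the real slope.
#'
#' @param real A `TrendPosterior` for the observed data.
#' @param null_slopes Null slopes paired 1:1 by sample index.
#' @return A `DriftResult`: list with `real`, `null`, `diff`, `p_drift`.
#' @export
p_drift <- function(real, null_slopes) {
  b <- if (inherits(real, "TrendPosterior")) real$slopes else as.numeric(real)
  d <- as.numeric(null_slopes)
  if (length(b) != length(d)) {
    stop("real and null slope counts differ (", length(b), " vs ", length(d), ")")
  }
  structure(list(real = b, null = d, diff = b - d, p_drift = mean(d > b)),
            class = "DriftResult")
}

#' @export
#' @method print DriftResult
print.DriftResult <- function(x, ...) {
  cat(sprintf("p_drift = %.3f over %d paired simulations (mean slope diff %.4f kg/yr)\n",
              x$p_drift, length(x$diff), mean(x$diff)))
  invisible(x)
}
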
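#' Mixture prior for the SNP-effect model
#'
#' Four normal components for SNP effects with variances equal to the stated
#' fractions of a reference variance (including a point mass at zero),
#' Dirichlet pseudo-counts over the components, and scaled inverse
#' chi-squared priors for the genetic and residual variances. The
#' conventional pseudo-counts are 1, 1, 1 and 5 with the 5 pseudo-observed
#' SNPs placed on the zero-effect class (most SNPs are expected to carry no
#' effect), so with components in ascending effect-variance order the
#' default vector is `c(5, 1, 1, 1)`.
#'
#' @param fractions Component effect variances as fractions of the reference
#'   variance, ascending from 0.
#' @param dirichlet Dirichlet pseudo-counts per component.
#' @param genetic_scale,genetic_df Scaled-inverse-chi-squared prior for the
#'   genetic variance (used when `reference = "genetic"`).
#' @param residual_scale,residual_df Prior for the residual variance.
#' @param reference Whether component variances scale the (fixed) phenotypic
#'   variance of the training phenotype or the (sampled) genetic variance
#'   parameter.
#' @return A `MixturePrior` list.
#' @export
mixture_prior <- function(fractions = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet = c(5, 1, 1, 1),
                          genetic_scale = 1.2, genetic_df = 10,
                          residual_scale = 2.5, residual_df = 10,
                          reference = c("phenotypic", "genetic")) {
  reference <- match.arg(reference)
  stopifnot(length(fractions) == length(dirichlet),
            fractions[1] == 0, !is.unsorted(fractions), all(dirichlet > 0))
  structure(list(fractions = fractions, dirichlet = dirichlet,
                 genetic_scale = genetic_scale, genetic_df = genetic_df,
                 residual_scale = residual_scale, residual_df = residual_df,
                 reference = reference),
            class = "MixturePrior")
}

#' MCMC settings
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Burn-in iterations discarded.
#' @param n_samples Number of posterior samples retained; the post-burn-in
#'   chain is evenly subsampled down to exactly this count.
#' @param seed Integer seed.
#' @return An `McmcSettings` list.
#' @export
mcmc_settings <- function(n_iter = 120000, burn_in = 20000, n_samples = 1000,
                          seed = 1) {
  stopifnot(burn_in < n_iter, n_iter - burn_in >= n_samples, n_samples >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "McmcSettings")
}

keep_iterations <- function(mcmc) {
  post <- mcmc$n_iter - mcmc$burn_in
  mcmc$burn_in + ceiling(seq_len(mcmc$n_samples) * post / mcmc$n_samples)
}

#' Fit the four-component mixture SNP-effect model
#'
#' Gibbs sampler over SNP effects (each SNP assigned one of four normal
#' components, the first a point mass at zero), mixture proportions
#' (Dirichlet), variances (scaled inverse chi-squared) and the intercept, on
#' the adjusted phenotypes of the training individuals. Genotypes are
#' mean-imputed and centered at twice the training allele frequency.
#'
#' @param train_phenos Data frame with columns `id` and `value` (adjusted
#'   phenotype, kg), e.g. `fit_repeatability_model(...)$phenotypes`.
#' @param g A `GenotypeSet` containing at least the training individuals.
#' @param prior A [mixture_prior()].
#' @param mcmc An [mcmc_settings()].
#' @return A `PosteriorChain`: list with `beta` (samples x SNPs, kg/allele),
#'   `comp` (mixture class per SNP and sample, 1 = zero class), `pi`,
#'   `mu`, `sigma2_e`, `sigma2_g`, `freq` (training allele frequencies used
#'   for centering), `snp_ids`, `train_ids`, `prior`, `mcmc`.
#' @export
fit_bayesr <- function(train_phenos, g, prior = mixture_prior(),
                       mcmc = mcmc_settings()) {
  ids <- as.character(train_phenos$id)
  if (!all(ids %in% rownames(g$geno))) {
    stop("training individuals not genotyped: ",
         paste(utils::head(setdiff(ids, rownames(g$geno)), 3), collapse = ", "))
  }
  y <- as.numeric(train_phenos$value)
  if (stats::var(y) == 0) stop("training phenotype variance is zero")
  freq <- allele_freq(g, ids)
  X <- centered_genotypes(g, ids, freq)
  set.seed(mcmc$seed)
  res <- bayesr_gibbs(X, y, prior$fractions, prior$dirichlet,
                      prior$reference == "genetic",
                      prior$genetic_df, prior$genetic_scale,
                      prior$residual_df, prior$residual_scale,
                      mcmc$n_iter, as.integer(keep_iterations(mcmc)))
  colnames(res$beta) <- colnames(res$comp) <- colnames(g$geno)
  structure(list(beta = res$beta, comp = res$comp, pi = res$pi, mu = res$mu,
                 sigma2_e = res$sigma2_e, sigma2_g = res$sigma2_g,
                 freq = freq, snp_ids = colnames(g$geno), train_ids = ids,
                 prior = prior, mcmc = mcmc),
            class = "PosteriorChain")
}

#' @export
#' @method print PosteriorChain
print.PosteriorChain <- function(x, ...) {
  cat(sprintf("PosteriorChain: %d samples x %d SNPs (training n = %d)\n",
              nrow(x$beta), ncol(x$beta), length(x$train_ids)))
  cat(sprintf("posterior mean sigma2_g = %.3f, sigma2_e = %.3f\n",
              mean(x$sigma2_g), mean(x$sigma2_e)))
  invisible(x)
}

#' Posterior genomic breeding values
#'
#' `value[i, s] = sum_j (g_ij - 2 p_j) beta_j^(s)` with the training
#' allele frequencies `p` stored in the chain, for training and test
#' individuals alike.
#'
#' @param chain A `PosteriorChain` from [fit_bayesr()].
#' @param g A `GenotypeSet`.
#' @param ids Individuals to predict (default: everyone genotyped).
#' @param birth_year Optional named vector (or `Pedigree`) supplying birth
#'   years for the result.
#' @return An `EbvPosterior`: list with `value` (individuals x samples, kg),
#'   `ids`, `birth_year`, `provenance = "genomic"`, `training` flag.
#' @export
predict_gebv <- function(chain, g, ids = rownames(g$geno), birth_year = NULL) {
  miss <- setdiff(ids, rownames(g$geno))
  if (length(miss) > 0) {
    stop("individuals not genotyped: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  stopifnot(identical(chain$snp_ids, colnames(g$geno)))
  X <- centered_genotypes(g, ids, chain$freq)
  value <- X %*% t(chain$beta)
  rownames(value) <- ids
  ebv_posterior(value, birth_year = birth_year, provenance = "genomic",
                training = ids %in% chain$train_ids)
}

#' Construct an EbvPosterior
#'
#' @param value Matrix individuals x posterior samples (kg).
#' @param birth_year Named vector of birth years, a `Pedigree`, or `NULL`.
#' @param provenance `"genomic"` or `"pedigree"`.
#' @param training Logical flag per individual (was its phenotype in the
#'   training data?).
#' @return An `EbvPosterior` list.
#' @export
ebv_posterior <- function(value, birth_year = NULL, provenance = "genomic",
                          training = NULL) {
  ids <- rownames(value)
  if (inherits(birth_year, "Pedigree")) {
    birth_year <- stats::setNames(birth_year$birth_year, birth_year$id)
  }
  by <- if (is.null(birth_year)) rep(NA_integer_, length(ids)) else
    unname(birth_year[ids])
  if (!all(is.finite(value))) stop("non-finite breeding values")
  structure(list(ids = ids, birth_year = as.integer(by),
                 value = value, provenance = provenance,
                 training = training %||% rep(NA, length(ids))),
            class = "EbvPosterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print EbvPosterior
print.EbvPosterior <- function(x, ...) {
  cat(sprintf("EbvPosterior (%s): %d individuals x %d posterior samples\n",
              x$provenance, nrow(x$value), ncol(x$value)))
  invisible(x)
}

#' Leave-one-cohort-out genomic prediction
#'
#' For each cohort, refits the SNP-effect model excluding every phenotype of
#' that cohort and takes the cohort's posterior breeding values from that fit,
#' so no individual's own phenotype, nor any phenotype of its birth cohort,
#' contributes to its prediction.
#'
#' @param phenos Adjusted phenotypes (`id`, `value`).
#' @param g A `GenotypeSet` covering all individuals to predict.
#' @param cohorts Named vector (or `Pedigree`) giving each individual's birth
#'   year; individuals without a cohort are predicted from the full fit of
#'   every training phenotype.
#' @param prior,mcmc As in [fit_bayesr()]; per-cohort chains derive their
#'   seeds deterministically from `mcmc$seed`.
#' @return An `EbvPosterior` assembled across cohorts.
#' @export
leave_one_cohort_out <- function(phenos, g, cohorts, prior = mixture_prior(),
                                 mcmc = mcmc_settings()) {
  if (inherits(cohorts, "Pedigree")) {
    cohorts <- stats::setNames(cohorts$birth_year, cohorts$id)
  }
  ids_all <- rownames(g$geno)
  coh <- cohorts[ids_all]
  uniq <- sort(unique(coh[as.character(phenos$id)]))
  if (length(uniq) < 2) stop("need at least 2 cohorts with phenotypes")
  value <- matrix(NA_real_, length(ids_all), mcmc$n_samples,
                  dimnames = list(ids_all, NULL))
  training <- rep(FALSE, length(ids_all))
  for (k in seq_along(uniq)) {
    cfit <- uniq[k]
    train <- phenos[coh[as.character(phenos$id)] != cfit, , drop = FALSE]
    if (nrow(train) == 0) stop("training set empty when leaving out cohort ", cfit)
    m_k <- mcmc
    m_k$seed <- as.integer((mcmc$seed + 7919 * k) %% .Machine$integer.max)
    chain_k <- fit_bayesr(train, g, prior, m_k)
    focal <- ids_all[!is.na(coh) & coh == cfit]
    if (length(focal) > 0) {
      value[focal, ] <- predict_gebv(chain_k, g, focal)$value
    }
  }
  rest <- ids_all[is.na(coh) | !(coh %in% uniq)]
  if (length(rest) > 0) {
    chain_full <- fit_bayesr(phenos, g, prior, mcmc)
    value[rest, ] <- predict_gebv(chain_full, g, rest)$value
  }
  ebv_posterior(value, birth_year = cohorts, provenance = "genomic",
                training = training)
}

#' Cross-validated accuracy of genomic prediction
#'
#' Splits the phenotyped individuals into `k_folds` folds; for each fold,
#' fits the SNP-effect model on the remaining folds, predicts posterior-mean
#' breeding values for the held-out individuals and correlates them with the
#' held-out adjusted phenotypes. Returns the fold-averaged correlation.
#'
#' @param phenos Adjusted phenotypes (`id`, `value`).
#' @param g A `GenotypeSet`.
#' @param k_folds Number of folds (>= 2).
#' @param prior,mcmc As in [fit_bayesr()].
#' @param seed Seed for the fold assignment.
#' @return The mean held-out correlation, with attribute `folds` (per-fold
#'   correlations).
#' @export
cv_accuracy <- function(phenos, g, k_folds = 5, prior = mixture_prior(),
                        mcmc = mcmc_settings(), seed = 1) {
  stopifnot(k_folds >= 2)
  set.seed(seed)
  n <- nrow(phenos)
  fold <- sample(rep_len(seq_len(k_folds), n))
  acc <- numeric(k_folds)
  for (k in seq_len(k_folds)) {
    test <- phenos[fold == k, , drop = FALSE]
    train <- phenos[fold != k, , drop = FALSE]
    if (nrow(test) == 0) stop("fold ", k, " has no phenotypes")
    m_k <- mcmc
    m_k$seed <- as.integer((mcmc$seed + 104729 * k) %% .Machine$integer.max)
    chain_k <- fit_bayesr(train, g, prior, m_k)
    pred <- rowMeans(predict_gebv(chain_k, g, as.character(test$id))$value)
    acc[k] <- stats::cor(pred, test$value)
  }
  structure(mean(acc), folds = acc)
}
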
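# small genotype panel with known LD-free structure
panel <- function(n, m, seed = 1, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.2, 0.8)
  geno <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(geno) <- list(sprintf("n%04d", seq_len(n)), sprintf("m%04d", seq_len(m)))
  genotype_set(geno)
}

test_that("pure-noise phenotypes land in the null component", {
  g <- panel(400, 150, seed = 2)
  set.seed(3)
  ph <- data.frame(id = rownames(g$geno), value = rnorm(400))
  chain <- fit_bayesr(ph, g, mixture_prior(), mcmc_settings(1200, 400, 100, seed = 5))
  # with no signal the small-variance classes are likelihood-indistinguishable
  # from the point mass, so the zero-class share is governed by its Dirichlet
  # pseudo-count share (5 of 8); it must be the modal class by a clear margin
  expect_gte(mean(chain$comp == 1), 0.5)
  tab <- table(factor(chain$comp, levels = 1:4))
  expect_identical(names(which.max(tab)), "1")
  # realized genetic variance a small fraction of the phenotypic variance
  expect_lt(mean(chain$sigma2_g), 0.1 * var(ph$value))
})

test_that("a single large-effect SNP is recovered near the ridge oracle", {
  g <- panel(500, 60, seed = 7)
  x <- g$geno[, 30]
  set.seed(8)
  b_true <- 1
  y <- b_true * x + rnorm(500, 0, sd(x))      # SNP explains ~50% of variance
  ph <- data.frame(id = rownames(g$geno), value = y)
  chain <- fit_bayesr(ph, g, mixture_prior(reference = "genetic"),
                      mcmc_settings(2000, 500, 200, seed = 9))
  bh <- chain$beta[, 30]
  # independent oracle: ridge (BLUP) estimate with a vanishing penalty is
  # the OLS coefficient of the centered predictor
  xc <- x - mean(x)
  b_ols <- sum(xc * y) / sum(xc^2)
  expect_lt(abs(mean(bh) - b_ols), 2 * sd(bh))
  expect_gt(mean(chain$comp[, 30] > 1), 0.95)  # detected as non-null
})

test_that("GEBV prediction is the centered genotype-effect product", {
  geno <- rbind(u = c(0L, 2L), v = c(1L, 1L), w = c(2L, 0L))
  colnames(geno) <- c("s1", "s2")
  g <- genotype_set(geno)
  chain <- structure(list(
    beta = rbind(c(0.5, -1), c(0, 0)),
    freq = c(s1 = 0.5, s2 = 0.5),
    snp_ids = c("s1", "s2"),
    train_ids = "u"), class = "PosteriorChain")
  eb <- predict_gebv(chain, g, birth_year = c(u = 2000L, v = 2000L, w = 2001L))
  # hand product: centered genotypes minus 2p = minus 1 per count
  Xc <- geno - 1
  expect_equal(unname(eb$value[, 1]), unname(drop(Xc %*% c(0.5, -1))))
  # an all-zero effect sample gives GEBV zero for everyone
  expect_true(all(eb$value[, 2] == 0))
  # one SNP, effect b, homozygote at p = 0.5 contributes exactly b
  chain1 <- structure(list(beta = matrix(0.7), freq = c(s1 = 0.5),
                           snp_ids = "s1", train_ids = character()),
                      class = "PosteriorChain")
  g1 <- genotype_set(matrix(2L, 1, 1, dimnames = list("z", "s1")))
  expect_equal(unname(predict_gebv(chain1, g1)$value[1, 1]), 0.7)
  expect_error(predict_gebv(chain1, g1, ids = "missing"), "not genotyped")
})

test_that("forcing the null component zeroes every breeding value", {
  g <- panel(120, 40, seed = 11)
  set.seed(12)
  ph <- data.frame(id = rownames(g$geno), value = rnorm(120))
  prior <- mixture_prior(dirichlet = c(1e9, 1e-4, 1e-4, 1e-4))
  chain <- fit_bayesr(ph, g, prior, mcmc_settings(400, 100, 50, seed = 13))
  expect_gt(mean(chain$comp == 1), 0.999)
  # in every retained sample the non-zero effect count equals m - #null
  nz <- rowSums(chain$beta != 0)
  null_n <- rowSums(chain$comp == 1)
  expect_true(all(nz == ncol(chain$beta) - null_n))
})

test_that("leave-one-cohort-out predictions ignore the focal phenotype", {
  g <- panel(150, 50, seed = 21)
  by <- setNames(rep(2001:2003, each = 50), rownames(g$geno))
  set.seed(22)
  ph <- data.frame(id = rownames(g$geno), value = rnorm(150))
  mc <- mcmc_settings(400, 100, 50, seed = 23)
  e1 <- leave_one_cohort_out(ph, g, by, mixture_prior(), mc)
  ph2 <- ph
  focal <- which(ph2$id == rownames(g$geno)[1])   # cohort 2001
  ph2$value[focal] <- ph2$value[focal] + 10
  e2 <- leave_one_cohort_out(ph2, g, by, mixture_prior(), mc)
  own <- rownames(g$geno)[1]
  expect_identical(e1$value[own, ], e2$value[own, ])
  # but predictions of other cohorts do change
  other <- rownames(g$geno)[51]
  expect_false(identical(e1$value[other, ], e2$value[other, ]))
  expect_error(leave_one_cohort_out(ph, g, setNames(rep(2001, 150), ph$id)),
               "2 cohorts")
})

test_that("cross-validated accuracy separates signal from noise", {
  st <- small_neutral_study(seed = 31)
  ids <- st$ped$id
  mc <- mcmc_settings(600, 200, 50, seed = 32)
  # phenotype = true BV exactly: accuracy should be high
  ph_sig <- data.frame(id = ids, value = st$bv[ids])
  acc_sig <- cv_accuracy(ph_sig, st$genotypes, k_folds = 3,
                         prior = mixture_prior(reference = "genetic"),
                         mcmc = mc, seed = 1)
  expect_gt(as.numeric(acc_sig), 0.6)
  # pure-noise phenotype: accuracy near zero
  set.seed(33)
  ph_noise <- data.frame(id = ids, value = rnorm(length(ids)))
  acc_noise <- cv_accuracy(ph_noise, st$genotypes, k_folds = 3,
                           prior = mixture_prior(), mcmc = mc, seed = 1)
  expect_lt(abs(as.numeric(acc_noise)), 0.25)
  expect_gt(as.numeric(acc_sig), as.numeric(acc_noise))
})

test_that("chain bookkeeping: thinning produces exactly the target samples", {
  k <- gebvtrend:::keep_iterations(mcmc_settings(120000, 20000, 1000))
  expect_length(k, 1000)
  expect_true(all(k > 20000 & k <= 120000))
  expect_equal(length(unique(k)), 1000)
  k2 <- gebvtrend:::keep_iterations(mcmc_settings(600000, 100000, 1000))
  expect_length(k2, 1000)
  expect_equal(diff(k2)[1], 500)    # 500000 / 1000 exactly
  expect_error(mcmc_settings(1000, 2000, 10))
  expect_error(mcmc_settings(1000, 900, 500))
})
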
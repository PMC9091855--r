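test_that("weighted slope matches closed-form hand computations", {
  expect_equal(weighted_slope(0:2, c(1, 2, 4)), 1.5)
  expect_equal(weighted_slope(0:2, c(1, 2, 4), c(2, 1, 1)), 16 / 11)
  expect_equal(weighted_slope(0:4, rep(3.2, 5)), 0)
  # equal weights reduce to ordinary least squares
  set.seed(1)
  x <- 1:8; y <- rnorm(8)
  expect_equal(weighted_slope(x, y), unname(coef(lm(y ~ x))[2]))
  expect_error(weighted_slope(c(2, 2), c(1, 2)), "identical")
})

test_that("cohort means average the right individuals and drop small cohorts", {
  v <- rbind(a = c(1, 2), b = c(3, 4), c = c(5, 6), d = c(7, 8))
  eb <- ebv_posterior(v, birth_year = c(a = 2000L, b = 2000L, c = 2001L,
                                        d = 2001L))
  cm <- cohort_means(eb, min_cohort_size = 1)
  expect_equal(cm$years, c(2000L, 2001L))
  expect_equal(unname(cm$means[1, ]), c(2, 3))   # mean of a, b per sample
  expect_equal(unname(cm$means[2, ]), c(6, 7))
  expect_equal(cm$sizes, c(2L, 2L))

  # an 80-individual cohort is dropped under the min-100 rule
  v2 <- matrix(0, 220, 2,
               dimnames = list(sprintf("i%03d", 1:220), NULL))
  by2 <- setNames(rep(c(2000L, 2001L, 2002L), c(80, 100, 40)),
                  rownames(v2))
  eb2 <- ebv_posterior(v2, birth_year = by2)
  expect_error(cohort_means(eb2, min_cohort_size = 100), "fewer than 2")
  cm2 <- cohort_means(eb2, min_cohort_size = 40)
  expect_equal(cm2$years, c(2000L, 2001L, 2002L))

  # single cohort below size: error
  expect_error(cohort_means(ebv_posterior(v[1:2, ], birth_year = c(a = 2000L, b = 2000L)),
                            min_cohort_size = 1), "fewer than 2")
})

test_that("posterior trend summarises slopes, CI and P(stasis)", {
  set.seed(3)
  n <- 300; S <- 400
  by <- setNames(rep(2001:2010, each = 30), sprintf("i%03d", 1:n))
  drift <- outer(by - 2005.5, rnorm(S, 0.011, 0.0048))
  v <- drift + matrix(rnorm(n * S, 0, 0.01), n, S)
  rownames(v) <- names(by)
  tr <- posterior_trend(ebv_posterior(v, birth_year = by), min_cohort_size = 10)
  # slopes recover the per-sample generating slopes; P_stasis ~ Phi(-mu/sd)
  expect_lt(abs(tr$summary$mean - 0.011), 0.002)
  expect_lt(abs(tr$summary$p_stasis - pnorm(-0.011 / 0.0048)), 0.05)
  expect_true(tr$summary$ci95[1] <= tr$summary$mean &&
                tr$summary$mean <= tr$summary$ci95[2])

  # all slopes exactly zero: stasis certain (boundary counts)
  v0 <- matrix(5, n, 4, dimnames = list(names(by), NULL))
  tr0 <- posterior_trend(ebv_posterior(v0, birth_year = by), min_cohort_size = 10)
  expect_equal(tr0$summary$p_stasis, 1)
  # strictly positive slopes in every sample: P_stasis = 0
  vpos <- outer(by - 2000, rep(1, 3)) + 0
  rownames(vpos) <- names(by)
  trp <- posterior_trend(ebv_posterior(vpos, birth_year = by), min_cohort_size = 10)
  expect_equal(trp$summary$p_stasis, 0)
})

test_that("trend slopes are location-invariant and scale-equivariant", {
  set.seed(8)
  by <- setNames(rep(2001:2008, each = 20), sprintf("x%03d", 1:160))
  v <- matrix(rnorm(160 * 50), 160, 50, dimnames = list(names(by), NULL))
  t1 <- posterior_trend(ebv_posterior(v, birth_year = by), min_cohort_size = 5)
  t2 <- posterior_trend(ebv_posterior(v + 7.3, birth_year = by), min_cohort_size = 5)
  t3 <- posterior_trend(ebv_posterior(v * -2.5, birth_year = by), min_cohort_size = 5)
  expect_equal(t1$slopes, t2$slopes, tolerance = 1e-10)
  expect_equal(t3$slopes, -2.5 * t1$slopes, tolerance = 1e-10)
})

test_that("Haldane rates follow the log-scale definition", {
  by <- setNames(rep(2001:2010, each = 20), sprintf("h%03d", 1:200))
  # constant EBVs: zero slope, zero Haldanes
  v0 <- matrix(1, 200, 5, dimnames = list(names(by), NULL))
  tr0 <- posterior_trend(ebv_posterior(v0, birth_year = by), min_cohort_size = 5)
  h0 <- haldane_rate(tr0, mean_trait = 24, trait_values_for_sd = rexp(100) + 20,
                     generation_time = 4)
  expect_equal(unname(h0$summary$mean), 0, tolerance = 1e-12)

  # deterministic slope: rate = slope_log * G / sd(log trait)
  v1 <- outer(0.01 * (by - 2001), rep(1, 3))
  rownames(v1) <- names(by)
  tr1 <- posterior_trend(ebv_posterior(v1, birth_year = by), min_cohort_size = 5)
  tv <- c(22, 23, 24, 25, 26)
  h1 <- haldane_rate(tr1, 24, tv, generation_time = 4)
  slope_log <- weighted_slope(tr1$years, log(24 + 0.01 * (tr1$years - 2001)),
                              tr1$sizes)
  expect_equal(unname(h1$rates[1]), slope_log * 4 / sd(log(tv)),
               tolerance = 1e-10)
  # doubling the generation time doubles the rate
  h2 <- haldane_rate(tr1, 24, tv, generation_time = 8)
  expect_equal(h2$rates, 2 * h1$rates, tolerance = 1e-12)
  expect_error(haldane_rate(tr1, -1, tv, 4))
})
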
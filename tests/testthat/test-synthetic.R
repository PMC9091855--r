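test_that("simulated pedigrees validate and respect demography", {
  ped <- simulate_pedigree(n_founders = 40, n_years = 8, seed = 3)
  # passes the same validation the file reader applies
  expect_silent(gebvtrend:::validate_pedigree(ped))
  expect_equal(sort(unique(ped$birth_year[1:40])), 1L)
  expect_gt(length(unique(ped$birth_year)), 4)

  # one year only: founders, nobody else
  ped1 <- simulate_pedigree(n_founders = 10, n_years = 1, seed = 1)
  expect_equal(nrow(ped1), 10)
  expect_true(all(is.na(ped1$sire)))

  # guaranteed survival and fecundity: every post-maturity cohort non-empty
  ped2 <- simulate_pedigree(n_founders = 10, n_years = 6, mean_offspring = 2,
                            survival_prob = 1, seed = 2)
  expect_true(all(3:6 %in% ped2$birth_year))

  # extinction is reported, not silently produced
  expect_error(simulate_pedigree(n_founders = 4, n_years = 12,
                                 mean_offspring = 0.1, survival_prob = 0.05,
                                 seed = 1),
               "extinct")
})

test_that("founder haplotype pool matches target frequencies and LD structure", {
  map <- make_genetic_map(200, n_chr = 2, rec = 0.5)   # fully unlinked
  pool <- simulate_founder_haplotypes(300, map, maf_beta_params = c(60, 60),
                                      seed = 5)
  p_real <- colMeans(pool)
  # realized frequencies match each site's drawn target within binomial
  # sampling error of the 600-haplotype pool (marginals are exact)
  expect_lt(max(abs(p_real - attr(pool, "freq"))), 5 * sqrt(0.25 / 600))
  expect_lt(abs(mean(p_real) - 0.5), 0.02)
  # adjacent unlinked SNPs: haplotype correlation near zero
  r_adj <- sapply(seq(1, 99), function(j) abs(cor(pool[, j], pool[, j + 1])))
  expect_lt(median(r_adj), 0.1)

  # tight linkage: strong LD between neighbours, decaying with distance
  map2 <- make_genetic_map(200, n_chr = 2, rec = 0.002)
  pool2 <- simulate_founder_haplotypes(300, map2, seed = 5)
  r2_adj <- sapply(seq(1, 99), function(j) cor(pool2[, j], pool2[, j + 1])^2)
  r2_far <- sapply(seq(1, 59), function(j) cor(pool2[, j], pool2[, j + 40])^2)
  expect_gt(mean(r2_adj), mean(r2_far))
  # strong mean association at r ~ 0 (pairs with mismatched frequencies cap
  # the attainable r2, so the average sits well below 1)
  expect_gt(mean(r2_adj), 0.3)
  # frequency-matched mid-range pairs approach the maximum
  pfr <- attr(pool2, "freq")
  mid <- which(abs(pfr[1:99] - 0.5) < 0.1 & abs(pfr[2:100] - 0.5) < 0.1 &
                 abs(pfr[1:99] - pfr[2:100]) < 0.05)
  expect_gt(mean(r2_adj[mid]), 0.75)
})

test_that("architecture assignment hits the genic variance target exactly", {
  p <- runif(1000, 0.1, 0.9)
  spec <- architecture_spec(1000, proportions = c(0.9, 0.05, 0.03, 0.02),
                            sigma2_A = 2.6)
  beta <- assign_architecture(spec, p, seed = 11)
  expect_equal(sum(2 * p * (1 - p) * beta^2), 2.6, tolerance = 1e-12)

  # all SNPs in the null component: effects exactly zero (zero target)
  spec0 <- architecture_spec(100, proportions = c(1, 0, 0, 0), sigma2_A = 0)
  expect_true(all(assign_architecture(spec0, p[1:100], seed = 1) == 0))
  # but a positive target with no mass outside the null class is an error
  specbad <- architecture_spec(100, proportions = c(1, 0, 0, 0), sigma2_A = 2)
  expect_error(assign_architecture(specbad, p[1:100], seed = 1), "non-null")

  # a single non-null SNP carries the whole target
  spec1 <- architecture_spec(1, proportions = c(0, 0, 0, 1), sigma2_A = 1.7)
  b1 <- assign_architecture(spec1, 0.3, seed = 2)
  expect_equal(2 * 0.3 * 0.7 * b1^2, 1.7, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("phenotype simulation reproduces its deterministic skeleton", {
  ped <- simulate_pedigree(n_founders = 30, n_years = 6, seed = 9)
  map <- make_genetic_map(50, n_chr = 2)
  pool <- simulate_founder_haplotypes(30, map, seed = 9)
  geno <- matrix(0L, nrow(ped), 50, dimnames = list(ped$id, map$snp_id))
  g <- genotype_set(geno, map = map)
  beta <- rep(0, 50)
  model0 <- trait_model(sigma2_A = 0, sigma2_PE = 0, sigma2_BY = 0,
                        sigma2_CY = 0, sigma2_E = 0)
  sim <- simulate_phenotypes(ped, g, beta, model0, seed = 1)
  expect_gt(nrow(sim$records), 0)
  ae <- model0$age_effects
  expected <- model0$mu +
    ifelse(sim$records$sex == "M", model0$sex_effect, 0) +
    gebvtrend:::age_effect_of(model0, floor(sim$records$capture_age / 12))
  expect_equal(sim$records$weight, expected, tolerance = 1e-12)
})

test_that("heritability is recovered from the simulated records", {
  # sigma2_PE = sigma2_BY = sigma2_CY = 0: regression of single-record
  # phenotype on true BV has slope ~1 and R2 ~ h2
  st <- simulate_study(n_founders = 250, n_years = 10, n_snps = 200, n_chr = 4,
                       model = trait_model(sigma2_A = 2.6, sigma2_PE = 0,
                                           sigma2_BY = 0, sigma2_CY = 0,
                                           sigma2_E = 7.8),
                       seed = 13)
  rec <- st$records[!duplicated(st$records$id), ]   # first adult record each
  fit <- lm(rec$weight ~ st$bv[rec$id] + factor(rec$sex))
  sl <- coef(fit)[2]
  expect_gt(sl, 0.85)
  expect_lt(sl, 1.15)
  h2_hat <- var(st$bv[rec$id]) * sl^2 /
    var(resid(lm(rec$weight ~ factor(rec$sex))))
  expect_gt(h2_hat, 0.15)
  expect_lt(h2_hat, 0.35)
})

test_that("transmission is Mendelian and studies are seed-deterministic", {
  st <- small_neutral_study(seed = 17)
  tp <- attr(st$ped, "true_parents")
  h1 <- st$genotypes$haplotypes$hap1
  h2 <- st$genotypes$haplotypes$hap2
  kids <- tp$id[!is.na(tp$sire)]
  for (id in kids) {
    s <- tp$sire[match(id, tp$id)]
    d <- tp$dam[match(id, tp$id)]
    expect_true(all(h1[id, ] == h1[s, ] | h1[id, ] == h2[s, ]), info = id)
    expect_true(all(h2[id, ] == h1[d, ] | h2[id, ] == h2[d, ]), info = id)
  }
  # phased haplotypes sum to genotypes by construction (container invariant)
  expect_identical(h1 + h2, st$genotypes$geno)

  st2 <- small_neutral_study(seed = 17)
  expect_identical(st$genotypes$geno, st2$genotypes$geno)
  expect_identical(st$records, st2$records)
  expect_identical(st$bv, st2$bv)
  st3 <- small_neutral_study(seed = 18)
  expect_false(identical(st$genotypes$geno, st3$genotypes$geno))
})

test_that("neutral cohorts carry no systematic breeding-value trend", {
  slopes <- sapply(1:25, function(s) {
    st <- small_neutral_study(seed = 100 + s)
    coh <- st$truth$cohort
    weighted_slope(coh$cohort, coh$mean_bv, coh$n)
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("viability selection produces a positive genetic trend", {
  slopes <- sapply(1:10, function(s) {
    st <- do.call(simulate_study, c(study_design("cryptic"), list(seed = 200 + s)))
    coh <- st$truth$cohort
    weighted_slope(coh$cohort, coh$mean_bv, coh$n)
  })
  expect_gt(mean(slopes), 0)
  expect_gt(mean(slopes > 0), 0.8)
})
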
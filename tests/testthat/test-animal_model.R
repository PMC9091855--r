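test_that("no additive signal yields near-zero heritability mass", {
  st <- simulate_study(n_founders = 150, n_years = 12, n_snps = 60, n_chr = 2,
                       survival_prob = 0.85,
                       model = trait_model(sigma2_A = 0, sigma2_PE = 1,
                                           sigma2_BY = 0.5, sigma2_CY = 0.5,
                                           sigma2_E = 5),
                       prop_unknown_sire = 0, prop_unknown_dam = 0, seed = 5)
  expect_true(all(st$bv == 0))
  am <- fit_animal_model(st$records, st$ped,
                         mcmc = mcmc_settings(2500, 800, 150, seed = 6))
  expect_lt(mean(am$h2), 0.08)
})

test_that("heritable simulations are recovered with sensible EBVs", {
  st <- simulate_study(n_founders = 150, n_years = 10, n_snps = 120, n_chr = 3,
                       model = trait_model(sigma2_A = 3, sigma2_PE = 1,
                                           sigma2_BY = 0.5, sigma2_CY = 0.5,
                                           sigma2_E = 5),
                       seed = 5)
  am <- fit_animal_model(st$records, st$ped,
                         mcmc = mcmc_settings(2500, 1000, 150, seed = 6))
  h2_true <- 3 / 10
  ci <- quantile(am$h2, c(0.025, 0.975))
  expect_gt(mean(am$h2), 0.1)
  expect_lt(mean(am$h2), 0.5)
  expect_true(ci[1] <= h2_true + 0.1 && ci[2] >= h2_true - 0.1)
  # posterior-mean EBVs track the simulated truth
  pm <- rowMeans(am$ebv$value)
  expect_gt(cor(pm, st$bv[am$ebv$ids]), 0.4)
  # unphenotyped founders shrink toward zero relative to phenotyped animals
  unph <- setdiff(st$ped$id, unique(st$records$id))
  if (length(unph) > 10) {
    expect_lt(mean(abs(pm[unph])), mean(abs(pm[unique(st$records$id)])))
  }
})

test_that("restricting the reported EBVs does not change the model", {
  st <- simulate_study(n_founders = 80, n_years = 6, n_snps = 40, n_chr = 2,
                       seed = 7)
  keep <- st$ped$id[seq(1, nrow(st$ped), by = 2)]
  am1 <- fit_animal_model(st$records, st$ped,
                          mcmc = mcmc_settings(400, 100, 50, seed = 8))
  am2 <- fit_animal_model(st$records, st$ped,
                          mcmc = mcmc_settings(400, 100, 50, seed = 8),
                          restrict_ids = keep)
  expect_identical(am1$varcomp, am2$varcomp)
  common <- intersect(rownames(am1$ebv$value), rownames(am2$ebv$value))
  expect_identical(am1$ebv$value[common, ], am2$ebv$value[common, ])
  expect_true(all(rownames(am2$ebv$value) %in% keep))
})

test_that("unphenotyped offspring EBVs regress on the midparent mean", {
  st <- simulate_study(n_founders = 150, n_years = 10, n_snps = 80, n_chr = 2,
                       model = trait_model(sigma2_A = 3, sigma2_PE = 0.5,
                                           sigma2_BY = 0.3, sigma2_CY = 0.3,
                                           sigma2_E = 4),
                       seed = 11)
  am <- fit_animal_model(st$records, st$ped,
                         mcmc = mcmc_settings(1500, 500, 100, seed = 12))
  pm <- rowMeans(am$ebv$value)
  ped <- st$ped
  phen <- unique(st$records$id)
  sel <- !is.na(ped$sire) & !is.na(ped$dam) & !(ped$id %in% phen) &
    ped$sire %in% names(pm) & ped$dam %in% names(pm)
  if (sum(sel) > 20) {
    mid <- (pm[ped$sire[sel]] + pm[ped$dam[sel]]) / 2
    b <- coef(lm(pm[ped$id[sel]] ~ mid))[2]
    expect_gt(b, 0.7)
    expect_lt(b, 1.3)
  }
})
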
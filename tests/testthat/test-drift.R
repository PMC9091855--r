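test_that("gene drops transmit intact haplotypes when recombination is off", {
  ped <- random_pedigree(n = 40, n_founders = 12, seed = 2)
  map <- genetic_map(chr = rep("c1", 30), snp_id = sprintf("q%02d", 1:30),
                     pos = 1:30, rec_next = rep(0, 30))
  pool <- simulate_founder_haplotypes(12, map, seed = 3)
  cfg <- gene_drop_config(founder_year_cutoff = 2, seed = 4)
  g <- gene_drop(ped, pool, map, cfg)
  # with r = 0 inside the single chromosome every genotype row must be the
  # sum of two pool haplotypes (gametes are intact pool haplotypes)
  pool_keys <- apply(pool, 1, paste, collapse = "")
  geno <- g$geno
  ok <- apply(geno, 1, function(row) {
    any(vapply(seq_len(nrow(pool)), function(a) {
      rem <- row - pool[a, ]
      all(rem %in% c(0L, 1L)) && paste(rem, collapse = "") %in% pool_keys
    }, logical(1)))
  })
  expect_true(all(ok))
})

test_that("gene-dropped offspring alleles are Mendelian (10k transmissions)", {
  set.seed(5)
  m <- 60
  sw <- c(0, runif(m - 1, 0, 0.4))
  hapA <- rbinom(m, 1, 0.5); hapB <- rbinom(m, 1, 0.5)
  violations <- 0L
  for (i in 1:170) {   # 170 gametes x 60 loci > 10000 transmissions
    gam <- meiosis_cpp(hapA, hapB, sw)
    violations <- violations + sum(gam != hapA & gam != hapB)
  }
  expect_identical(violations, 0L)
})

test_that("drift conserves expected allele frequency over replicate drops", {
  ped <- random_pedigree(n = 120, n_founders = 20, seed = 6)
  map <- make_genetic_map(10, n_chr = 1, rec = 0.1)
  set.seed(7)
  pool <- matrix(rbinom(40 * 10, 1, 0.3), 40, 10,
                 dimnames = list(NULL, map$snp_id))
  cfg <- gene_drop_config(founder_year_cutoff = 2)
  last <- ped$id[ped$birth_year >= 10]
  freqs <- sapply(1:400, function(s) {
    g <- gene_drop(ped, pool, map, cfg, seed = s)
    mean(g$geno[last, 1]) / 2
  })
  p0 <- mean(pool[, 1])
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - p0), 3 * se + 1e-9)
})

test_that("missing parents fall back to donors of the right sex and era", {
  ped <- as_pedigree(data.frame(
    id = c("m1", "f1", "m2", "f2", "kid"),
    sire = c(NA, NA, NA, NA, NA),          # kid's sire unrecorded
    dam = c(NA, NA, NA, NA, "f2"),
    sex = c("M", "F", "M", "F", "F"),
    birth_year = c(1, 1, 4, 4, 8)))
  donors <- gebvtrend:::donor_candidates(
    ped[gebvtrend:::pedigree_order(ped), ], gene_drop_config(founder_year_cutoff = 2))
  ord_ids <- ped$id[gebvtrend:::pedigree_order(ped)]
  kid_idx <- match("kid", ord_ids)
  # male donors born 2-10 years before year 8: only m2 qualifies (m1 is 7
  # years earlier and also within the window, both male)
  cand_ids <- ord_ids[donors$sire[[kid_idx]]]
  expect_true(all(cand_ids %in% c("m1", "m2")))
  expect_true("m2" %in% cand_ids)
  # dam recorded, so no dam donors
  expect_length(donors$dam[[kid_idx]], 0)

  # the drop runs and yields complete genotypes
  map <- make_genetic_map(12, n_chr = 2, rec = 0.1)
  pool <- simulate_founder_haplotypes(6, map, seed = 1)
  g <- gene_drop(ped, pool, map, gene_drop_config(founder_year_cutoff = 2), seed = 2)
  expect_false(anyNA(g$geno))
  expect_error(gene_drop(ped, pool[0, , drop = FALSE], map,
                         gene_drop_config(founder_year_cutoff = 2)), "empty")
})

test_that("genomic null slopes are zero when effects are zero and the fast
          path equals the gene_drop + predict_gebv route", {
  st <- small_neutral_study(seed = 41)
  map <- st$genotypes$map
  pool <- haplotype_pool(st$genotypes)
  cfg <- gene_drop_config(founder_year_cutoff = 2005, seed = 6)
  chain0 <- structure(list(
    beta = matrix(0, 4, ncol(pool)), freq = st$freq,
    snp_ids = map$snp_id, train_ids = character()), class = "PosteriorChain")
  z <- drift_null_genomic(st$ped, pool, map, chain0, cfg, min_cohort_size = 5)
  expect_true(all(z == 0))

  set.seed(42)
  chain1 <- chain0
  chain1$beta <- matrix(rnorm(3 * ncol(pool), 0, 0.05), 3)
  fast <- drift_null_genomic(st$ped, pool, map, chain1, cfg, min_cohort_size = 5)
  slow <- sapply(1:3, function(s) {
    g_s <- gene_drop(st$ped, pool, map, cfg,
                     seed = as.integer((cfg$seed + 1000003 * s) %% .Machine$integer.max))
    eb <- predict_gebv(chain1, g_s, birth_year = st$ped)
    cm <- cohort_means(eb, NULL, 5)
    weighted_slope(cm$years, cm$means[, s], cm$sizes)
  })
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("pedigree drift null follows the midparent transmission model", {
  ped <- random_pedigree(n = 200, n_founders = 40, seed = 8)
  # zero additive variance: all null slopes exactly zero
  z <- drift_null_pedigree(ped, rep(0, 5), seed = 1, min_cohort_size = 5)
  expect_true(all(z == 0))
  expect_error(drift_null_pedigree(ped, c(1, -1), seed = 1), "negative")

  # founder BVs have variance sigma2_A across replicates
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  s2 <- 2.5
  sims <- sapply(1:300, function(s) {
    bvs <- gebvtrend:::drift_bv_once(ped, s2, seed = 100 + s)
    var(bvs[founders])
  })
  expect_lt(abs(mean(sims) - s2), 3 * sd(sims) / sqrt(length(sims)))

  # drift accumulates: late-cohort mean-BV variance exceeds the founder
  # cohort's over replicates
  early <- ped$id[ped$birth_year <= 1]
  late <- ped$id[ped$birth_year >= 10]
  mm <- sapply(1:300, function(s) {
    bvs <- gebvtrend:::drift_bv_once(ped, s2, seed = 500 + s)
    c(mean(bvs[early]), mean(bvs[late]))
  })
  expect_gt(var(mm[2, ]), var(mm[1, ]))
})

test_that("p_drift counts strict exceedances over paired simulations", {
  tr <- structure(list(slopes = c(1, 2, 3, 4)), class = "TrendPosterior")
  expect_equal(p_drift(tr, c(2, 1, 4, 3))$p_drift, 0.5)
  expect_equal(p_drift(tr, c(0, 0, 0, 0))$p_drift, 0)
  expect_equal(p_drift(tr, c(1, 2, 3, 4))$p_drift, 0)   # ties are not exceedances
  expect_equal(p_drift(tr, c(9, 9, 9, 9))$p_drift, 1)
  expect_error(p_drift(tr, c(1, 2)), "differ")
  expect_equal(p_drift(tr, c(2, 1, 4, 3))$diff, c(-1, 1, -1, 1))
})
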
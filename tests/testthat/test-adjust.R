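make_records <- function(n_id, n_rec, s2_id = 3, s2_by = 1, s2_cy = 1,
                         s2_e = 4, seed = 1) {
  set.seed(seed)
  id <- sprintf("a%04d", seq_len(n_id))
  birth <- sample(2000:2007, n_id, replace = TRUE)
  sex <- sample(c("M", "F"), n_id, replace = TRUE)
  u_id <- rnorm(n_id, 0, sqrt(s2_id))
  years <- 2000:2015
  u_by <- setNames(rnorm(length(years), 0, sqrt(s2_by)), years)
  u_cy <- setNames(rnorm(length(years), 0, sqrt(s2_cy)), years)
  rows <- do.call(rbind, lapply(seq_len(n_id), function(i) {
    ages <- 2:(1 + n_rec)
    cy <- birth[i] + ages
    data.frame(id = id[i], weight = 24 + 2 * (sex[i] == "M") + u_id[i] +
                 u_by[as.character(birth[i])] + u_cy[as.character(cy)] +
                 rnorm(n_rec, 0, sqrt(s2_e)),
               capture_age = ages * 12 + 4, capture_year = cy,
               capture_month = 8L, sex = sex[i])
  }))
  list(records = rows, u_id = setNames(u_id, id))
}

test_that("degenerate and shifted inputs behave as the model implies", {
  rec <- data.frame(id = rep(c("x", "y"), each = 3), weight = 20,
                    capture_age = rep(c(28, 40, 52), 2),
                    capture_year = rep(2001:2003, 2), capture_month = 8,
                    sex = rep(c("F", "M"), each = 3))
  fit0 <- fit_repeatability_model(rec)
  expect_true(all(fit0$phenotypes$value == 0))
  expect_true(all(fit0$varcomp == 0))

  sim <- make_records(120, 3, seed = 4)
  f1 <- fit_repeatability_model(sim$records)
  rec2 <- sim$records
  rec2$weight <- rec2$weight + 100     # absorbed by the intercept
  f2 <- fit_repeatability_model(rec2)
  expect_equal(f1$phenotypes$value, f2$phenotypes$value, tolerance = 1e-6)
  expect_equal(unname(f2$fixef["(Intercept)"] - f1$fixef["(Intercept)"]), 100,
               tolerance = 1e-6)
})

test_that("variance components are recovered on data simulated from the model", {
  sim <- make_records(500, 3, s2_id = 3, s2_by = 1, s2_cy = 1, s2_e = 4,
                      seed = 99)
  fit <- fit_repeatability_model(sim$records)
  vc <- fit$varcomp
  # rough large-sample SEs: id ~ sqrt(2/n)*s2-ish; year terms have ~14 levels
  expect_lt(abs(vc["sigma2_ID"] - 3), 3 * 3 * sqrt(2 / 500))
  expect_lt(abs(vc["sigma2_E"] - 4), 3 * 4 * sqrt(2 / 1000))
  expect_lt(abs(vc["sigma2_BY"] - 1), 1.2)   # few levels: wide interval
  expect_lt(abs(vc["sigma2_CY"] - 1), 1.2)
  # BLUPs track the true individual effects
  expect_gt(cor(fit$phenotypes$value, sim$u_id[fit$phenotypes$id]), 0.6)
})

test_that("BLUPs shrink toward zero relative to raw fixed-effect deviations", {
  # year variances zero so the identity effect is the only random deviation
  sim <- make_records(150, 3, s2_by = 0, s2_cy = 0, seed = 21)
  fit <- fit_repeatability_model(sim$records)
  d <- sim$records
  d$age_years <- floor(d$capture_age / 12)
  raw <- resid(lm(weight ~ sex + factor(age_years), data = d))
  raw_mean <- tapply(raw, d$id, mean)
  v <- setNames(fit$phenotypes$value, fit$phenotypes$id)
  common <- names(raw_mean)
  expect_true(all(abs(v[common]) <= abs(raw_mean[common]) + 0.02))
})

test_that("single records without year variance give proportional residuals", {
  set.seed(5)
  n <- 200
  rec <- data.frame(id = sprintf("s%03d", 1:n),
                    weight = 24 + rnorm(n, 0, 2),
                    capture_age = 40, capture_year = 2005, capture_month = 8,
                    sex = "F")
  fit <- suppressWarnings(fit_repeatability_model(rec))
  resd <- rec$weight - mean(rec$weight)
  ratio <- fit$phenotypes$value / resd[match(fit$phenotypes$id, rec$id)]
  expect_lt(diff(range(ratio)), 1e-6)          # one common shrinkage factor
  expect_gt(ratio[1], 0)
  expect_lt(ratio[1], 1)
})

test_that("deregression undoes BLUP shrinkage on average", {
  sim <- make_records(400, 3, seed = 31)
  plain <- fit_repeatability_model(sim$records)
  dereg <- fit_repeatability_model(sim$records, deregress = TRUE)
  b_plain <- coef(lm(plain$phenotypes$value ~ sim$u_id[plain$phenotypes$id]))[2]
  b_dereg <- coef(lm(dereg$phenotypes$value ~ sim$u_id[dereg$phenotypes$id]))[2]
  expect_lt(b_plain, 0.95)
  expect_gt(b_dereg, b_plain)
  expect_lt(abs(b_dereg - 1), 0.2)
})
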
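#' Evenly spaced synthetic genetic map
#'
#' @param n_snps Total SNP count.
#' @param n_chr Number of chromosomes (SNPs split as evenly as possible).
#' @param rec Recombination fraction between adjacent SNPs within a
#'   chromosome.
#' @return A `GeneticMap`.
#' @export
make_genetic_map <- function(n_snps, n_chr = 5, rec = 0.02) {
  chr <- sort(rep_len(seq_len(n_chr), n_snps))
  pos <- stats::ave(seq_len(n_snps), chr, FUN = seq_along)
  genetic_map(chr = sprintf("chr%02d", chr),
              snp_id = sprintf("snp%05d", seq_len(n_snps)),
              pos = pos, rec_next = rep(rec, n_snps))
}

#' Simulate an overlapping-generation pedigree
#'
#' Discrete-year demography over `n_years` cohorts: founders are born in the
#' first year; every later year, each surviving female of at least the
#' maturity age produces a Poisson number of offspring, each sired by a random
#' surviving mature male (polygyny permitted). Individuals survive each winter
#' independently with probability `survival_prob`.
#'
#' @param n_founders Number of founders (split evenly by sex), >= 2.
#' @param n_years Number of cohort years.
#' @param mean_offspring Mean offspring per mature female per year.
#' @param survival_prob Annual survival probability.
#' @param maturity_age Minimum age (years) for reproduction.
#' @param prop_unknown_sire,prop_unknown_dam Probability that a parent link is
#'   censored (recorded as unknown) in the returned pedigree, emulating
#'   incomplete paternity/maternity assignment. Transmission in downstream
#'   joint simulations always uses the true parent.
#' @param seed Integer seed.
#' @return A `Pedigree` with attributes `death_year` (named integer vector)
#'   and `true_parents` (data frame with the uncensored links).
#' @export
simulate_pedigree <- function(n_founders = 200, n_years = 15,
                              mean_offspring = 1.0, survival_prob = 0.75,
                              maturity_age = 2, prop_unknown_sire = 0,
                              prop_unknown_dam = 0, seed = 1) {
  set.seed(seed)
  eng <- demography_engine(n_founders, n_years, mean_offspring, survival_prob,
                           maturity_age)
  finish_pedigree(eng, prop_unknown_sire, prop_unknown_dam)
}


finish_pedigree <- function(eng, prop_unknown_sire, prop_unknown_dam) {
  n <- eng$n
  ids <- sprintf("ind%05d", seq_len(n))
  sire_id <- ifelse(eng$sire > 0, ids[pmax(eng$sire, 1L)], NA_character_)
  dam_id <- ifelse(eng$dam > 0, ids[pmax(eng$dam, 1L)], NA_character_)
  true_parents <- data.frame(id = ids, sire = sire_id, dam = dam_id,
                             stringsAsFactors = FALSE)
  mask_s <- !is.na(sire_id) & stats::runif(n) < prop_unknown_sire
  mask_d <- !is.na(dam_id) & stats::runif(n) < prop_unknown_dam
  sire_id[mask_s] <- NA_character_
  dam_id[mask_d] <- NA_character_
  ped <- as_pedigree(data.frame(id = ids, sire = sire_id, dam = dam_id,
                                sex = eng$sex, birth_year = eng$birth,
                                stringsAsFactors = FALSE))
  death <- eng$death
  names(death) <- ids
  attr(ped, "death_year") <- death[ped$id]
  attr(ped, "true_parents") <- true_parents
  ped
}

#' Simulate a pool of LD-structured founder haplotypes
#'
#' Per-SNP reference-allele frequencies are drawn from a Beta distribution.
#' Each haplotype is generated by a first-order latent process along the SNP
#' order: a standard-normal AR(1) chain with lag correlation `1 - 2r` for the
#' interval recombination fraction `r`, thresholded at the per-SNP normal
#' quantile of the allele frequency (a Gaussian-copula chain). Marginal
#' frequencies are therefore exact Bernoulli(p_j); allelic association
#' between neighbouring SNPs approaches its maximum given the frequencies as
#' `r -> 0`, vanishes at `r = 0.5`, and decays monotonically (geometrically)
#' with map distance in between.
#'
#' @param n_founders Number of founder individuals (pool holds `2 * n_founders`
#'   haplotypes).
#' @param map A `GeneticMap`.
#' @param maf_beta_params Shape parameters of the Beta distribution of
#'   reference-allele frequencies.
#' @param min_maf Frequencies are clamped to `[min_maf, 1 - min_maf]` so no
#'   site is monomorphic by construction.
#' @param seed Integer seed.
#' @return Integer matrix `2*n_founders` x n_snps of 0/1 alleles, with
#'   attribute `freq` = the frequencies the sites were drawn at.
#' @export
simulate_founder_haplotypes <- function(n_founders, map,
                                        maf_beta_params = c(2, 2),
                                        min_maf = 0.05, seed = 1) {
  set.seed(seed)
  m <- nrow(map)
  H <- 2L * n_founders
  p <- stats::rbeta(m, maf_beta_params[1], maf_beta_params[2])
  p <- pmin(pmax(p, min_maf), 1 - min_maf)
  sw <- switch_probs(map)
  rho <- pmax(1 - 2 * sw, 0)       # latent lag correlation per interval
  z <- matrix(stats::rnorm(H * m), H, m)
  x <- z
  for (j in 2:m) {
    x[, j] <- rho[j] * x[, j - 1] + sqrt(1 - rho[j]^2) * z[, j]
  }
  thr <- stats::qnorm(p)
  pool <- matrix(0L, H, m)
  for (j in seq_len(m)) pool[, j] <- as.integer(x[, j] < thr[j])
  dimnames(pool) <- list(NULL, map$snp_id)
  attr(pool, "freq") <- stats::setNames(p, map$snp_id)
  pool
}

#' Architecture specification for simulated SNP effects
#'
#' @param n_snps SNP count.
#' @param fractions Variance of each mixture component as a fraction of the
#'   reference variance.
#' @param proportions Fraction of SNPs in each component (sums to 1).
#' @param ref_var Reference variance (kg^2) the fractions scale; by default
#'   the rescaling to `sigma2_A` makes only the ratios matter.
#' @param sigma2_A Target total additive genic variance (kg^2).
#' @return An `ArchitectureSpec` list.
#' @export
architecture_spec <- function(n_snps, fractions = c(0, 1e-4, 1e-3, 1e-2),
                              proportions = c(0.9, 0.05, 0.03, 0.02),
                              ref_var = 10.5, sigma2_A = 2.6) {
  stopifnot(length(fractions) == length(proportions),
            abs(sum(proportions) - 1) < 1e-8, all(fractions >= 0),
            all(proportions >= 0), sigma2_A >= 0)
  structure(list(n_snps = n_snps, fractions = fractions,
                 proportions = proportions, ref_var = ref_var,
                 sigma2_A = sigma2_A),
            class = "ArchitectureSpec")
}

#' Assign mixture-architecture effects to SNPs
#'
#' Each SNP is assigned a mixture component with the spec's proportions and an
#' effect drawn from Normal(0, fraction x reference variance); non-null
#' effects are then rescaled so the realized additive genic variance
#' `sum(2 p (1-p) beta^2)` equals the spec's `sigma2_A` exactly.
#'
#' @param spec An [architecture_spec()].
#' @param allele_freqs Reference-allele frequency per SNP.
#' @param seed Integer seed.
#' @return Numeric vector of per-allele effects (kg), with attribute
#'   `component` (integer class per SNP, 1 = null).
#' @export
assign_architecture <- function(spec, allele_freqs, seed = 1) {
  set.seed(seed)
  m <- spec$n_snps
  stopifnot(length(allele_freqs) == m)
  comp <- sample.int(length(spec$proportions), m, replace = TRUE,
                     prob = spec$proportions)
  sds <- sqrt(spec$fractions * spec$ref_var)
  beta <- stats::rnorm(m, 0, sds[comp])
  genic <- sum(2 * allele_freqs * (1 - allele_freqs) * beta^2)
  if (genic > 0) {
    beta <- beta * sqrt(spec$sigma2_A / genic)   # a zero target zeroes all
  } else if (spec$sigma2_A > 0) {
    stop("no non-null SNP effects drawn but sigma2_A > 0; ",
         "increase non-null proportions")
  }
  names(beta) <- names(allele_freqs)
  attr(beta, "component") <- comp
  beta
}

#' Trait model for the phenotype simulator
#'
#' Variance components and fixed-effect profile of the simulated trait
#' (August adult body weight, kg). Defaults give a phenotypic variance of
#' about 10.5 kg^2 and h2 of about 0.25, a plausible configuration for a
#' moderately heritable size trait with repeated annual measures.
#'
#' @param mu Population mean weight (kg) for an adult female at the baseline
#'   age class.
#' @param sigma2_A,sigma2_PE,sigma2_BY,sigma2_CY,sigma2_E Additive genetic,
#'   permanent-environment, birth-year, capture-year and residual variances
#'   (kg^2).
#' @param sex_effect Additive male effect (kg).
#' @param age_effects Named vector of age-class effects (kg) by whole years of
#'   age; ages beyond the last named class receive the last value.
#' @param env_trend Deterministic linear trend in the capture-year effect
#'   (kg/yr); a negative value creates the environmental decline of a
#'   cryptic-evolution regime.
#' @param regime `"neutral"` or `"viability"`.
#' @param viability_strength Log-odds increase in annual survival per kg of
#'   body weight above the current population mean (only used under the
#'   viability regime).
#' @return A `TraitModel` list.
#' @export
trait_model <- function(mu = 24, sigma2_A = 2.6, sigma2_PE = 1.5,
                        sigma2_BY = 0.8, sigma2_CY = 0.6, sigma2_E = 5,
                        sex_effect = 3,
                        age_effects = c("2" = 0, "3" = 1.2, "4" = 1.8, "5" = 2.1),
                        env_trend = 0, regime = c("neutral", "viability"),
                        viability_strength = 0.2) {
  regime <- match.arg(regime)
  vars <- c(sigma2_A, sigma2_PE, sigma2_BY, sigma2_CY, sigma2_E)
  stopifnot(all(vars >= 0))
  structure(list(mu = mu, sigma2_A = sigma2_A, sigma2_PE = sigma2_PE,
                 sigma2_BY = sigma2_BY, sigma2_CY = sigma2_CY,
                 sigma2_E = sigma2_E, sex_effect = sex_effect,
                 age_effects = age_effects, env_trend = env_trend,
                 regime = regime, viability_strength = viability_strength),
            class = "TraitModel")
}

age_effect_of <- function(model, age_years) {
  ages <- as.integer(names(model$age_effects))
  idx <- pmin(pmax(age_years, ages[1]), ages[length(ages)])
  unname(model$age_effects[match(idx, ages)])
}

#' Simulate phenotype records on a fixed pedigree
#'
#' Computes true breeding values from the supplied genotypes and effects and
#' builds repeated August capture records: weight = mu + sex + age class + BV
#' + permanent environment + birth-year effect + capture-year effect
#' (including the deterministic environmental trend) + residual, one record
#' per year the individual is alive at or beyond the minimum age.
#'
#' Because the pedigree (and hence reproduction) is fixed here, the viability
#' regime only filters which records exist (weight-dependent survival); a
#' cryptic-evolution regime in which selection feeds back into who breeds is
#' produced by [simulate_study()], which co-simulates demography, inheritance
#' and phenotypes.
#'
#' @param ped A `Pedigree` with a `death_year` attribute (as produced by
#'   [simulate_pedigree()]); without it, all individuals are assumed alive to
#'   the last cohort year.
#' @param genotypes A `GenotypeSet` covering all pedigree ids.
#' @param effects Per-allele effects (kg) as from [assign_architecture()].
#' @param model A [trait_model()].
#' @param freq Allele frequencies used to center genotypes when computing true
#'   breeding values (defaults to the observed frequencies).
#' @param min_age_years First age class measured (2 years, i.e. 28 months at
#'   an August capture for a spring-born animal).
#' @param seed Integer seed.
#' @return List with `records` (phenotype data frame), `bv` (named true
#'   breeding values), and `year_effects` (the birth/capture year draws).
#' @export
simulate_phenotypes <- function(ped, genotypes, effects, model,
                                freq = allele_freq(genotypes),
                                min_age_years = 2, seed = 1) {
  set.seed(seed)
  X <- centered_genotypes(genotypes, ids = ped$id, freq = freq)
  bv <- drop(X %*% effects)
  names(bv) <- ped$id
  years <- seq(min(ped$birth_year), max(ped$birth_year))
  comp <- draw_phenotype_components(ped, years, model)
  death <- attr(ped, "death_year")
  if (is.null(death)) death <- stats::setNames(rep(max(years) + 1L, nrow(ped)), ped$id)
  records <- build_records(ped, bv, comp, model, years, death, min_age_years)
  list(records = records, bv = bv,
       year_effects = list(birth = comp$by_eff, capture = comp$cy_eff),
       pe = comp$pe)
}

draw_phenotype_components <- function(ped, years, model) {
  list(
    pe = stats::setNames(stats::rnorm(nrow(ped), 0, sqrt(model$sigma2_PE)), ped$id),
    by_eff = stats::setNames(stats::rnorm(length(years), 0, sqrt(model$sigma2_BY)), years),
    cy_eff = stats::setNames(stats::rnorm(length(years), 0, sqrt(model$sigma2_CY)) +
                               model$env_trend * (years - mean(years)), years)
  )
}

# expected August weight (no residual) of individuals at a given capture year
expected_weight <- function(ped, bv, comp, model, year) {
  age <- year - ped$birth_year
  model$mu + ifelse(ped$sex == "M", model$sex_effect, 0) +
    age_effect_of(model, age) + bv[ped$id] + comp$pe[ped$id] +
    comp$by_eff[as.character(ped$birth_year)] +
    comp$cy_eff[as.character(year)]
}

build_records <- function(ped, bv, comp, model, years, death, min_age_years) {
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    year <- years[k]
    age <- year - ped$birth_year
    live <- death[ped$id] >= year   # alive at the August catch of `year`
    sel <- which(age >= min_age_years & live)
    if (length(sel) == 0) next
    ew <- expected_weight(ped[sel, , drop = FALSE], bv, comp, model, year)
    out[[k]] <- data.frame(
      id = ped$id[sel],
      weight = ew + stats::rnorm(length(sel), 0, sqrt(model$sigma2_E)),
      capture_age = 12L * age[sel] + 4L,
      capture_year = year,
      capture_month = 8L,
      sex = ped$sex[sel],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, out)
  if (is.null(rec)) {
    rec <- data.frame(id = character(), weight = numeric(),
                      capture_age = integer(), capture_year = integer(),
                      capture_month = integer(), sex = character())
  }
  rownames(rec) <- NULL
  rec
}

#' Co-simulate a complete synthetic study
#'
#' Joint forward simulation of demography, haplotype inheritance and
#' phenotypes, so that under the viability regime weight-dependent winter
#' survival feeds back into who survives to reproduce, producing a genuine
#' genetic trend across cohorts; combined with a negative environmental trend
#' in the capture-year effects this emulates cryptic microevolution (genetic
#' gain masked by phenotypic decline).
#'
#' @param n_founders,n_years,mean_offspring,survival_prob,maturity_age
#'   Demography, as in [simulate_pedigree()].
#' @param n_snps,n_chr,rec Genome, as in [make_genetic_map()].
#' @param arch An [architecture_spec()] (its `n_snps` is overridden).
#' @param model A [trait_model()]; set `regime = "viability"` plus a negative
#'   `env_trend` for the cryptic regime.
#' @param prop_unknown_sire,prop_unknown_dam Parent-link censoring in the
#'   recorded pedigree.
#' @param first_year Calendar year of the first cohort (cosmetic offset).
#' @param min_age_years First measured age class.
#' @param seed Integer master seed.
#' @return A `SimulatedStudy` list: `ped`, `genotypes` (phased, with map),
#'   `effects`, `bv`, `records`, `pool`, `freq`, `model`, `truth` (cohort
#'   table with mean true BV per cohort) and `seed`.
#' @export
simulate_study <- function(n_founders = 200, n_years = 15,
                           mean_offspring = 1.0, survival_prob = 0.75,
                           maturity_age = 2, n_snps = 500, n_chr = 5,
                           rec = 0.02,
                           arch = architecture_spec(n_snps,
                                                    sigma2_A = model$sigma2_A),
                           model = trait_model(),
                           prop_unknown_sire = 0.1, prop_unknown_dam = 0.02,
                           first_year = 2001L, min_age_years = 2,
                           seed = 1) {
  set.seed(seed)
  if (abs(arch$sigma2_A - model$sigma2_A) > 1e-8) {
    warning("architecture sigma2_A (", arch$sigma2_A,
            ") differs from the trait model's (", model$sigma2_A,
            "); the architecture target is what the genotypes realize")
  }
  map <- make_genetic_map(n_snps, n_chr = n_chr, rec = rec)
  pool <- simulate_founder_haplotypes(n_founders, map,
                                      seed = sample.int(2^31 - 1, 1))
  p <- attr(pool, "freq")
  arch$n_snps <- n_snps
  effects <- assign_architecture(arch, p, seed = sample.int(2^31 - 1, 1))
  sw <- switch_probs(map)
  m <- n_snps

  # growing haplotype stores, column = individual, plus per-individual state
  cap <- n_founders + 64L
  hap1 <- matrix(0L, m, cap); hap2 <- matrix(0L, m, cap)
  bv <- numeric(cap); pe <- numeric(cap)
  env <- new.env(parent = emptyenv())
  env$hap1 <- hap1; env$hap2 <- hap2; env$bv <- bv; env$pe <- pe
  env$eng <- NULL
  center <- sum(2 * p * effects)

  years <- seq_len(n_years)
  by_eff <- stats::rnorm(n_years, 0, sqrt(model$sigma2_BY))
  cy_eff <- stats::rnorm(n_years, 0, sqrt(model$sigma2_CY)) +
    model$env_trend * (years - mean(years))

  pool_cursor <- local({i <- 0L; function(k) {
    # founders cycle through the pool haplotypes without replacement
    idx <- ((i + seq_len(k) - 1L) %% ncol(env$pool_t)) + 1L
    i <<- i + k
    idx
  }})
  env$pool_t <- t(pool)   # m x H

  grow <- function(need) {
    while (need > ncol(env$hap1)) {
      env$hap1 <- cbind(env$hap1, matrix(0L, m, ncol(env$hap1)))
      env$hap2 <- cbind(env$hap2, matrix(0L, m, ncol(env$hap2)))
      env$bv <- c(env$bv, numeric(length(env$bv)))
      env$pe <- c(env$pe, numeric(length(env$pe)))
    }
  }

  # demography callback: assign haplotypes/BV/PE at birth
  on_birth <- function(idx, founder) {
    grow(max(idx))
    if (founder) {
      a <- pool_cursor(length(idx)); b <- pool_cursor(length(idx))
      env$hap1[, idx] <- env$pool_t[, a]
      env$hap2[, idx] <- env$pool_t[, b]
    } else {
      transmit_inplace(env$hap1, env$hap2, idx, env$sire_now[idx],
                       env$dam_now[idx], sw)
    }
    g <- env$hap1[, idx, drop = FALSE] + env$hap2[, idx, drop = FALSE]
    env$bv[idx] <- drop(crossprod(g, effects)) - center
    env$pe[idx] <- stats::rnorm(length(idx), 0, sqrt(model$sigma2_PE))
  }

  # the engine exposes sire/dam of the batch being born through env
  eng <- demography_engine(n_founders, n_years, mean_offspring, survival_prob,
                           maturity_age, env, on_birth, model, by_eff, cy_eff)

  ped <- finish_pedigree(eng, prop_unknown_sire, prop_unknown_dam)
  n <- eng$n
  ids <- sprintf("ind%05d", seq_len(n))
  # reorder everything to pedigree row order
  ord <- match(ped$id, ids)
  h1 <- t(env$hap1[, ord, drop = FALSE]); h2 <- t(env$hap2[, ord, drop = FALSE])
  dimnames(h1) <- dimnames(h2) <- list(ped$id, map$snp_id)
  geno <- h1 + h2
  genotypes <- genotype_set(geno, haplotypes = list(hap1 = h1, hap2 = h2),
                            map = map)
  bv_all <- stats::setNames(env$bv[ord], ped$id)
  comp <- list(pe = stats::setNames(env$pe[ord], ped$id),
               by_eff = stats::setNames(by_eff, years),
               cy_eff = stats::setNames(cy_eff, years))
  death <- attr(ped, "death_year")
  records <- build_records(ped, bv_all, comp, model, years, death,
                           min_age_years)
  # cosmetic calendar offset
  offset <- as.integer(first_year) - 1L
  ped$birth_year <- ped$birth_year + offset
  attr(ped, "death_year") <- death + offset
  records$capture_year <- records$capture_year + offset
  names(comp$by_eff) <- names(comp$cy_eff) <- years + offset

  cohort <- stats::aggregate(list(mean_bv = bv_all),
                             by = list(cohort = ped$birth_year), FUN = mean)
  cohort$n <- as.integer(table(ped$birth_year)[as.character(cohort$cohort)])
  list(ped = ped, genotypes = genotypes, effects = effects, bv = bv_all,
       records = records, pool = pool, freq = p, model = model,
       components = comp, truth = list(cohort = cohort), seed = seed)
}

# year-by-year demography with optional birth/viability hooks; under the
# viability regime winter survival is logistic in latent expected weight
demography_engine <- function(n_founders, n_years, mean_offspring,
                              survival_prob, maturity_age, env = NULL,
                              on_birth = NULL, model = NULL, by_eff = NULL,
                              cy_eff = NULL) {
  stopifnot(n_founders >= 2)
  cap <- n_founders + 64L
  sex <- character(cap); sex[seq_len(n_founders)] <- rep_len(c("M", "F"), n_founders)
  birth <- integer(cap); birth[seq_len(n_founders)] <- 1L
  sire <- integer(cap); dam <- integer(cap)
  death <- integer(cap)
  n <- n_founders
  alive <- seq_len(n_founders)
  if (!is.null(on_birth)) {
    env$sire_now <- sire; env$dam_now <- dam
    on_birth(seq_len(n_founders), founder = TRUE)
  }
  for (year in seq_len(n_years)) {
    if (year > 1) {
      age <- year - birth[alive]
      females <- alive[sex[alive] == "F" & age >= maturity_age]
      males <- alive[sex[alive] == "M" & age >= maturity_age]
      if (length(females) > 0 && length(males) > 0) {
        n_off <- stats::rpois(length(females), mean_offspring)
        mothers <- rep(females, n_off)
        if (length(mothers) > 0) {
          fathers <- males[sample.int(length(males), length(mothers), replace = TRUE)]
          k <- length(mothers)
          while (n + k > cap) {
            cap2 <- cap * 2L
            sex <- c(sex, character(cap)); birth <- c(birth, integer(cap))
            sire <- c(sire, integer(cap)); dam <- c(dam, integer(cap))
            death <- c(death, integer(cap)); cap <- cap2
          }
          idx <- n + seq_len(k)
          sex[idx] <- sample(c("M", "F"), k, replace = TRUE)
          birth[idx] <- year
          sire[idx] <- fathers
          dam[idx] <- mothers
          n <- n + k
          alive <- c(alive, idx)
          if (!is.null(on_birth)) {
            env$sire_now <- sire; env$dam_now <- dam
            on_birth(idx, founder = FALSE)
          }
        }
      }
    }
    p_surv <- rep(survival_prob, length(alive))
    if (!is.null(model) && model$regime == "viability" && length(alive) > 1) {
      # viability selection acts on the heritable and cohort components of
      # weight (deviation from the age/sex expectation). Selecting on the
      # permanent-environment or residual components as well would add a
      # survivor-collider covariance between breeding values and
      # environmental deviations, biasing downstream effect estimation; the
      # regime is designed to test trend recovery, not that bias.
      w <- env$bv[alive] + by_eff[birth[alive]]
      p_surv <- stats::plogis(stats::qlogis(survival_prob) +
                                model$viability_strength * (w - mean(w)))
    }
    lives <- stats::runif(length(alive)) < p_surv
    death[alive[!lives]] <- year
    alive <- alive[lives]
    if (length(alive) == 0 && year < n_years) {
      stop("population went extinct in year ", year,
           "; increase survival_prob or mean_offspring")
    }
  }
  death[alive] <- n_years + 1L
  list(n = n, sex = sex[seq_len(n)], birth = birth[seq_len(n)],
       sire = sire[seq_len(n)], dam = dam[seq_len(n)],
       death = death[seq_len(n)])
}

#' Canonical synthetic study designs
#'
#' Two frozen parameter sets used throughout the analyses and tests:
#' `"neutral"` (no selection, no environmental trend; the null regime for
#' drift-test calibration: a strong founder bottleneck of 60 individuals
#' growing to roughly 800-1000 over 15 cohorts, 500 SNPs with moderate LD,
#' so that genetic drift dominates estimation noise) and `"cryptic"` (viability selection on the
#' heritable component of weight producing a genetic gain of roughly
#' 0.02-0.04 kg/yr, masked by a deterministic environmental decline of
#' -0.22 kg/yr carried by strong capture-year effects; a larger population
#' with an oligogenic-leaning architecture so that desk-scale marker counts
#' reach the prediction accuracy regime of a well-powered study).
#'
#' @param regime `"neutral"` or `"cryptic"`.
#' @return Named list of [simulate_study()] arguments (pass a `seed` when
#'   calling, e.g. `do.call(simulate_study, c(study_design("cryptic"),
#'   list(seed = 1)))`).
#' @export
study_design <- function(regime = c("neutral", "cryptic")) {
  regime <- match.arg(regime)
  if (regime == "neutral") {
    list(n_founders = 60, n_years = 15, mean_offspring = 1.4,
         survival_prob = 0.8, n_snps = 500, n_chr = 5, rec = 0.01,
         arch = architecture_spec(500, proportions = c(0.98, 0, 0, 0.02)),
         model = trait_model(sigma2_PE = 0.5, sigma2_E = 3))
  } else {
    list(n_founders = 400, n_years = 15, mean_offspring = 0.8,
         survival_prob = 0.82, n_snps = 300, n_chr = 10, rec = 0.05,
         arch = architecture_spec(300, proportions = c(0.98, 0, 0, 0.02)),
         model = trait_model(sigma2_PE = 0.5, sigma2_E = 3, sigma2_BY = 0.05,
                             sigma2_CY = 2.25, env_trend = -0.25,
                             regime = "viability", viability_strength = 0.06))
  }
}
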
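# Shared in-code fixtures and independent oracles.

trio_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("s1", "d1", "c1"),
    sire = c(NA, NA, "s1"),
    dam = c(NA, NA, "d1"),
    sex = c("M", "F", "F"),
    birth_year = c(2000L, 2000L, 2002L)
  ))
}

# write a small pedigree file and return its path
write_ped_file <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ped.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small genotype set with known counts
toy_genotypes <- function(geno = rbind(i1 = c(1L, 0L), i2 = c(2L, 2L)),
                          snps = paste0("s", seq_len(ncol(geno)))) {
  colnames(geno) <- snps
  genotype_set(geno)
}

# independent HWE exact-test oracle: enumerate all heterozygote counts with
# matching parity and sum probabilities computed straight from the
# conditional distribution written with choose()
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  pr <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    exp(lchoose(n, naa) + lchoose(n - naa, h) + h * log(2) -
          lchoose(2 * n, na))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# dense tabular numerator relationship matrix (recursive definition); the
# independent oracle for the sparse Henderson A-inverse
tabular_A <- function(ped) {
  ped <- ped[order(ped$birth_year, ped$id), , drop = FALSE]
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    for (j in seq_len(i - 1)) {
      aij <- 0
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

# random valid pedigree for property tests
random_pedigree <- function(n = 50, n_founders = 10, seed = 1) {
  set.seed(seed)
  id <- sprintf("p%03d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  birth <- c(rep(1L, n_founders),
             sort(sample(2:12, n - n_founders, replace = TRUE)))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    males <- which(sex == "M" & birth < birth[i])
    females <- which(sex == "F" & birth < birth[i])
    if (length(males) > 0 && stats::runif(1) < 0.9) {
      sire[i] <- id[males[sample.int(length(males), 1)]]
    }
    if (length(females) > 0 && stats::runif(1) < 0.9) {
      dam[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                         birth_year = birth))
}

# compact neutral synthetic study for fast tests
small_neutral_study <- function(seed = 1, ...) {
  simulate_study(n_founders = 80, n_years = 10, n_snps = 120, n_chr = 3,
                 model = trait_model(), seed = seed, ...)
}
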
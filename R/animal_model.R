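#' Bayesian animal model on raw repeated measures
#'
#' Gibbs sampler for the mixed model
#' `weight = sex + age + animal + permanent environment + birth year +
#' capture year + residual`, where the animal effect has covariance
#' `A sigma2_A` structured by the pedigree numerator relationship matrix.
#' Location parameters are sampled jointly from their multivariate normal
#' full conditional via a sparse Cholesky solve of the mixed-model equations;
#' variances from scaled-inverse-chi-squared full conditionals.
#'
#' Breeding values are sampled for every pedigree member, so unphenotyped
#' individuals (e.g. a genotyped test population) receive posterior EBVs
#' through their relatives.
#'
#' @param records Phenotype data frame (`id`, `weight`, `sex`, `capture_age`
#'   in months, `capture_year`); every phenotyped id must be in the pedigree.
#' @param ped A validated `Pedigree`.
#' @param mcmc An [mcmc_settings()]; the conventional full-scale setting for
#'   this model is `mcmc_settings(600000, 100000, 1000)`.
#' @param priors Scaled-inverse-chi-squared priors: list with `df` and
#'   `scale` applied to each variance component; `scale = NULL` uses
#'   `var(weight) / 20` with one prior degree of freedom (weakly
#'   informative; components with few levels, like birth and capture year,
#'   are especially sensitive to stronger prior scales).
#' @param restrict_ids Optional ids to which the returned `EbvPosterior` is
#'   restricted (e.g. genotyped individuals only); the model itself always
#'   uses the full pedigree.
#' @param age One of `"factor"` or `"poly"`, as in
#'   [fit_repeatability_model()].
#' @return List of class `AnimalModelChain` with `ebv` (an `EbvPosterior`,
#'   provenance `"pedigree"`), `varcomp` (samples x 5 matrix: `sigma2_A`,
#'   `sigma2_PE`, `sigma2_BY`, `sigma2_CY`, `sigma2_E`), `fixef` (samples x
#'   fixed effects) and `h2` (per-sample narrow-sense heritability).
#' @export
fit_animal_model <- function(records, ped, mcmc = mcmc_settings(30000, 5000, 1000),
                             priors = list(df = 1, scale = NULL),
                             restrict_ids = NULL, age = c("factor", "poly")) {
  age <- match.arg(age)
  d <- as.data.frame(records)
  stopifnot(nrow(d) >= 2)
  if (!all(d$id %in% ped$id)) {
    stop("phenotyped ids missing from pedigree: ",
         paste(utils::head(setdiff(d$id, ped$id), 3), collapse = ", "))
  }
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  ain <- a_inverse(ped)
  Ainv <- ain$Ainv
  q <- nrow(ped)

  d$age_years <- floor(d$capture_age / 12)
  y <- d$weight
  nobs <- length(y)
  vy <- stats::var(y)
  if (vy == 0) stop("phenotype variance is zero")
  s0 <- priors$scale %||% (vy / 20)
  df0 <- priors$df

  # fixed effects: intercept + sex + age
  sex_f <- factor(d$sex)
  age_f <- factor(d$age_years)
  Xl <- list(`(Intercept)` = rep(1, nobs))
  if (nlevels(sex_f) > 1) Xl$sex <- as.numeric(sex_f == levels(sex_f)[2])
  X <- do.call(cbind, Xl)
  colnames(X) <- names(Xl)
  if (nlevels(age_f) > 1) {
    if (age == "factor") {
      Xa <- stats::model.matrix(~ age_f)[, -1, drop = FALSE]
    } else {
      Xa <- stats::poly(d$age_years, 2)
    }
    X <- cbind(X, Xa)
  }
  X <- Matrix::Matrix(X, sparse = TRUE)
  nf <- ncol(X)

  ids_ph <- factor(d$id, levels = unique(d$id))
  Za <- Matrix::sparseMatrix(i = seq_len(nobs), j = match(d$id, ped$id),
                             x = 1, dims = c(nobs, q))
  Zpe <- Matrix::fac2sparse(ids_ph)
  Zpe <- Matrix::t(Zpe)
  npe <- ncol(Zpe)
  by_f <- factor(ped$birth_year[match(d$id, ped$id)])
  cy_f <- factor(d$capture_year)
  Zby <- Matrix::t(Matrix::fac2sparse(by_f)); nby <- ncol(Zby)
  Zcy <- Matrix::t(Matrix::fac2sparse(cy_f)); ncy <- ncol(Zcy)

  W <- cbind(X, Za, Zpe, Zby, Zcy)
  WtW <- Matrix::crossprod(W)
  Wty <- Matrix::crossprod(W, y)
  p_tot <- ncol(W)
  blocks <- list(fix = seq_len(nf),
                 a = nf + seq_len(q),
                 pe = nf + q + seq_len(npe),
                 by = nf + q + npe + seq_len(nby),
                 cy = nf + q + npe + nby + seq_len(ncy))

  set.seed(mcmc$seed)
  # initial values
  s2 <- c(A = vy / 5, PE = vy / 10, BY = vy / 10, CY = vy / 10, E = vy / 2)
  theta <- numeric(p_tot)
  keep <- keep_iterations(mcmc)
  S <- length(keep)
  out_var <- matrix(NA_real_, S, 5,
                    dimnames = list(NULL, c("sigma2_A", "sigma2_PE",
                                            "sigma2_BY", "sigma2_CY", "sigma2_E")))
  out_fix <- matrix(NA_real_, S, nf, dimnames = list(NULL, colnames(W)[blocks$fix]))
  out_a <- matrix(NA_real_, q, S)
  ch <- NULL
  Ieps <- Matrix::Diagonal(nf, 1e-8)   # flat prior on fixed effects
  kp <- 1L

  for (it in seq_len(mcmc$n_iter)) {
    G <- Matrix::bdiag(Ieps, Ainv / s2["A"],
                       Matrix::Diagonal(npe, 1 / s2["PE"]),
                       Matrix::Diagonal(nby, 1 / s2["BY"]),
                       Matrix::Diagonal(ncy, 1 / s2["CY"]))
    LHS <- WtW / s2["E"] + G
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(LHS), LDL = FALSE,
                             super = FALSE)
    } else {
      ch <- update(ch, Matrix::forceSymmetric(LHS))
    }
    mean_t <- Matrix::solve(ch, Wty / s2["E"], system = "A")
    z <- stats::rnorm(p_tot)
    u <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt")
    theta <- as.numeric(mean_t) + as.numeric(u)

    a <- theta[blocks$a]
    e <- y - as.numeric(W %*% theta)
    qa <- as.numeric(a %*% (Ainv %*% a))
    s2["A"] <- rscinv(df0 + q, (df0 * s0 + qa) / (df0 + q))
    s2["PE"] <- rscinv(df0 + npe, (df0 * s0 + sum(theta[blocks$pe]^2)) / (df0 + npe))
    s2["BY"] <- rscinv(df0 + nby, (df0 * s0 + sum(theta[blocks$by]^2)) / (df0 + nby))
    s2["CY"] <- rscinv(df0 + ncy, (df0 * s0 + sum(theta[blocks$cy]^2)) / (df0 + ncy))
    s2["E"] <- rscinv(df0 + nobs, (df0 * s0 + sum(e^2)) / (df0 + nobs))
    if (!all(is.finite(s2))) stop("animal-model sampler diverged at iteration ", it)

    if (kp <= S && it == keep[kp]) {
      out_var[kp, ] <- s2
      out_fix[kp, ] <- theta[blocks$fix]
      out_a[, kp] <- a
      kp <- kp + 1L
    }
  }

  rownames(out_a) <- ped$id
  if (!is.null(restrict_ids)) {
    out_a <- out_a[rownames(out_a) %in% restrict_ids, , drop = FALSE]
  }
  ebv <- ebv_posterior(out_a, birth_year = ped, provenance = "pedigree",
                       training = rownames(out_a) %in% d$id)
  h2 <- out_var[, "sigma2_A"] / rowSums(out_var)
  structure(list(ebv = ebv, varcomp = out_var, fixef = out_fix, h2 = h2,
                 mcmc = mcmc, Fcoef = ain$F),
            class = "AnimalModelChain")
}

rscinv <- function(nu, s2) nu * s2 / stats::rchisq(1, nu)

#' @export
#' @method print AnimalModelChain
print.AnimalModelChain <- function(x, ...) {
  cat(sprintf("AnimalModelChain: %d samples, %d individuals\n",
              nrow(x$varcomp), nrow(x$ebv$value)))
  cat(sprintf("posterior mean h2 = %.3f, sigma2_A = %.3f\n",
              mean(x$h2), mean(x$varcomp[, "sigma2_A"])))
  invisible(x)
}
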
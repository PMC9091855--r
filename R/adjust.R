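#' Stage-one repeatability model: adjusted phenotypes
#'
#' Fits the Gaussian mixed model
#' `weight ~ sex + age + (1|id) + (1|birth_year) + (1|capture_year)`
#' by REML and returns the best linear unbiased prediction of each
#' individual's identity effect as its adjusted phenotype, together with the
#' variance-component estimates. This is the first stage of the two-stage
#' analysis: downstream genomic prediction treats the individual effect as the
#' phenotype, so repeated measures, cohort environments and measurement-year
#' environments are absorbed here.
#'
#' @param records Phenotype data frame with columns `id`, `weight`, `sex`,
#'   `capture_age` (months), `capture_year`; `birth_year` is derived from
#'   capture year and age if absent.
#' @param age One of `"factor"` (whole years of age as a categorical effect,
#'   the default) or `"poly"` (quadratic polynomial in age).
#' @param deregress If `TRUE`, each BLUP is divided by its reliability
#'   `r2 = 1 - PEV / sigma2_ID` (deregressed proofs). BLUPs are shrunken
#'   toward zero in proportion to their reliability, which attenuates
#'   downstream SNP-effect and breeding-value scales; deregression restores
#'   the expectation of the individual's true deviation at the cost of extra
#'   noise for sparsely recorded individuals. The default keeps the plain
#'   BLUP.
#' @return List of class `AdjustedPhenotypes` with elements `phenotypes`
#'   (data frame: `id`, `value`, `n_records`), `varcomp` (named vector:
#'   `sigma2_ID`, `sigma2_BY`, `sigma2_CY`, `sigma2_E`), `fixef` and `fit`
#'   (the underlying `lmerMod`).
#' @export
fit_repeatability_model <- function(records, age = c("factor", "poly"),
                                    deregress = FALSE) {
  age <- match.arg(age)
  stopifnot(nrow(records) >= 2)
  d <- as.data.frame(records)
  if (length(unique(d$id)) < 2) stop("need at least 2 individuals")
  d$age_years <- floor(d$capture_age / 12)
  if (is.null(d$birth_year)) d$birth_year <- d$capture_year - d$age_years
  d$id <- factor(d$id)
  d$sex <- factor(d$sex)
  d$fBY <- factor(d$birth_year)
  d$fCY <- factor(d$capture_year)
  if (stats::var(d$weight) == 0) {
    # degenerate but legal: no variation, every component and BLUP is zero
    ids <- levels(d$id)
    phen <- data.frame(id = ids, value = 0,
                       n_records = as.integer(table(d$id)[ids]),
                       stringsAsFactors = FALSE)
    return(structure(list(phenotypes = phen,
                          varcomp = c(sigma2_ID = 0, sigma2_BY = 0,
                                      sigma2_CY = 0, sigma2_E = 0),
                          fixef = c(`(Intercept)` = d$weight[1]), fit = NULL),
                     class = "AdjustedPhenotypes"))
  }
  age_term <- if (age == "factor") "factor(age_years)" else "poly(age_years, 2)"
  sex_term <- if (nlevels(d$sex) > 1) "sex + " else ""
  age_ok <- length(unique(d$age_years)) > 1
  fixed <- paste0("weight ~ ", sex_term, if (age_ok) age_term else "1")
  # year terms need at least two sampled levels to be estimable
  res <- c("(1 | id)",
           if (nlevels(d$fBY) > 1) "(1 | fBY)",
           if (nlevels(d$fCY) > 1) "(1 | fCY)")
  form <- stats::as.formula(paste0(fixed, " + ", paste(res, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))
    )),
    error = function(e) stop("repeatability model failed to converge: ",
                             conditionMessage(e))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  varcomp <- c(sigma2_ID = getvc("id"), sigma2_BY = getvc("fBY"),
               sigma2_CY = getvc("fCY"), sigma2_E = getvc("Residual"))
  if (any(varcomp[c("sigma2_ID")] < 1e-10)) {
    warning("individual-identity variance estimated at the zero boundary")
  }
  re <- lme4::ranef(fit, condVar = TRUE)$id
  nrec <- table(d$id)
  value <- re[["(Intercept)"]]
  reliability <- rep(NA_real_, length(value))
  if (deregress) {
    pev <- attr(re, "postVar")[1, 1, ]
    reliability <- pmax(1 - pev / max(varcomp["sigma2_ID"], 1e-12), 0.1)
    value <- value / reliability
  }
  phen <- data.frame(id = rownames(re), value = value,
                     n_records = as.integer(nrec[rownames(re)]),
                     reliability = reliability,
                     stringsAsFactors = FALSE)
  rownames(phen) <- NULL
  structure(list(phenotypes = phen, varcomp = varcomp,
                 fixef = lme4::fixef(fit), fit = fit),
            class = "AdjustedPhenotypes")
}

#' @export
#' @method print AdjustedPhenotypes
print.AdjustedPhenotypes <- function(x, ...) {
  cat("Adjusted phenotypes for", nrow(x$phenotypes), "individuals\n")
  cat("Variance components (kg^2):\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Write adjusted phenotypes to TSV
#'
#' @param adj An `AdjustedPhenotypes` object.
#' @param path Output path.
#' @export
write_adjusted_phenotypes <- function(adj, path) {
  utils::write.table(adj$phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
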
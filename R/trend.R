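#' Per-sample cohort mean breeding values
#'
#' For each retained cohort (birth year) and posterior sample, the mean
#' breeding value over individuals born that year. Cohorts outside
#' `year_range` or smaller than `min_cohort_size` are excluded (and listed in
#' the `excluded` attribute).
#'
#' @param ebv An `EbvPosterior` carrying birth years.
#' @param year_range Length-2 vector `(first, last)` of birth years included,
#'   or `NULL` for all.
#' @param min_cohort_size Minimum individuals per cohort; the convention for
#'   the full-scale study design is 100, synthetic studies use smaller
#'   cohorts.
#' @return List with `means` (matrix, cohorts x samples), `years`, `sizes`.
#' @export
cohort_means <- function(ebv, year_range = NULL, min_cohort_size = 100) {
  by <- ebv$birth_year
  if (all(is.na(by))) stop("EbvPosterior carries no birth years")
  keep <- !is.na(by)
  if (!is.null(year_range)) {
    keep <- keep & by >= year_range[1] & by <= year_range[2]
  }
  v <- ebv$value[keep, , drop = FALSE]
  byk <- by[keep]
  sizes <- table(byk)
  retained <- names(sizes)[sizes >= min_cohort_size]
  excluded <- names(sizes)[sizes < min_cohort_size]
  if (length(retained) < 2) {
    stop("fewer than 2 cohorts of at least ", min_cohort_size,
         " individuals in the requested year range")
  }
  sel <- byk %in% as.integer(retained)
  grp <- factor(byk[sel], levels = sort(as.integer(retained)))
  sums <- rowsum(v[sel, , drop = FALSE], grp)
  n <- as.integer(table(grp))
  means <- sums / n
  structure(list(means = means, years = as.integer(levels(grp)), sizes = n),
            excluded = as.integer(excluded))
}

#' Weighted least-squares slope
#'
#' Slope of `y` on `x` with weights `w`:
#' `sum(w (x - xw)(y - yw)) / sum(w (x - xw)^2)` with weighted means `xw`,
#' `yw`.
#'
#' @param x Predictor (e.g. cohort years).
#' @param y Response (e.g. cohort mean EBVs), a vector or a matrix with one
#'   column per posterior sample.
#' @param w Positive weights (e.g. cohort sizes); equal weights give the OLS
#'   slope.
#' @return The slope (scalar, or vector across columns of `y`).
#' @export
weighted_slope <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) >= 2, all(w > 0))
  if (stats::var(x) == 0) stop("all x values identical; slope undefined")
  xw <- sum(w * x) / sum(w)
  cx <- x - xw
  denom <- sum(w * cx^2)
  if (is.matrix(y)) {
    stopifnot(nrow(y) == length(x))
    as.numeric(crossprod(w * cx, y)) / denom
  } else {
    stopifnot(length(y) == length(x))
    sum(w * cx * y) / denom
  }
}

#' Posterior trend of cohort mean breeding values
#'
#' Applies the size-weighted regression of cohort mean EBV on birth year to
#' every posterior sample, giving a posterior distribution of the trend
#' slope; summarised by its mean, percentile 95% credible interval and the
#' probability of stasis `P(slope <= 0)`.
#'
#' @param ebv An `EbvPosterior`.
#' @param year_range,min_cohort_size Passed to [cohort_means()].
#' @return A `TrendPosterior`: list with `slopes` (kg/yr per sample),
#'   `years`, `sizes`, `cohort_means` and `summary` (mean, `ci95`, `p_stasis`).
#' @export
posterior_trend <- function(ebv, year_range = NULL, min_cohort_size = 100) {
  cm <- cohort_means(ebv, year_range, min_cohort_size)
  slopes <- weighted_slope(cm$years, cm$means, cm$sizes)
  new_trend_posterior(slopes, cm)
}

new_trend_posterior <- function(slopes, cm) {
  ci <- unname(stats::quantile(slopes, c(0.025, 0.975)))
  structure(list(slopes = slopes, years = cm$years, sizes = cm$sizes,
                 cohort_means = cm$means,
                 summary = list(mean = mean(slopes), ci95 = ci,
                                p_stasis = mean(slopes <= 0))),
            class = "TrendPosterior")
}

#' @export
#' @method print TrendPosterior
print.TrendPosterior <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Trend over cohorts %d-%d: %.4f kg/yr (95%% CI %.4f to %.4f), P(stasis) = %.3f\n",
              min(x$years), max(x$years), s$mean, s$ci95[1], s$ci95[2],
              s$p_stasis))
  invisible(x)
}

#' Evolutionary rate in Haldanes
#'
#' Re-expresses the posterior breeding-value trend as trait standard
#' deviations per generation on the log scale: per posterior sample the
#' cohort trait scale is reconstructed as `mean_trait +` cohort mean EBV,
#' log-transformed and regressed on year with the cohort-size weights; the
#' per-year log-scale slope times the generation time, divided by the
#' standard deviation of the log-transformed trait values, is the rate in
#' Haldanes.
#'
#' @param trend A `TrendPosterior`.
#' @param mean_trait Overall mean trait value (kg) added to the cohort mean
#'   EBVs.
#' @param trait_values_for_sd Trait values (e.g. individual adult weights, or
#'   mean + individual EBVs) whose log-scale standard deviation scales the
#'   rate.
#' @param generation_time Mean generation interval in years.
#' @return List with `rates` (Haldanes per posterior sample) and `summary`
#'   (mean and 95% CI).
#' @export
haldane_rate <- function(trend, mean_trait, trait_values_for_sd,
                         generation_time) {
  stopifnot(generation_time > 0, mean_trait > 0)
  recon <- mean_trait + trend$cohort_means
  if (any(recon <= 0)) stop("non-positive reconstructed trait values; mean_trait too small")
  if (any(trait_values_for_sd <= 0)) stop("trait values must be positive for the log scale")
  sd_log <- stats::sd(log(trait_values_for_sd))
  log_slopes <- weighted_slope(trend$years, log(recon), trend$sizes)
  rates <- log_slopes * generation_time / sd_log
  list(rates = rates,
       summary = list(mean = mean(rates),
                      ci95 = unname(stats::quantile(rates, c(0.025, 0.975))),
                      sd_log = sd_log, generation_time = generation_time))
}
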
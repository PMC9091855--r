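#' Phenotypic trend of sex/age-adjusted weights
#'
#' Regression of capture-year mean weight, corrected for sex and age class by
#' a fixed-effects fit, on capture year, weighting each year by its number of
#' records. This is the phenotypic counterpart of the breeding-value trends:
#' under cryptic evolution it moves in the opposite direction.
#'
#' @param records Phenotype records (`id`, `weight`, `sex`, `capture_age`,
#'   `capture_year`).
#' @return List with `slope` (kg/yr), `years`, `means`, `sizes`.
#' @export
phenotypic_trend <- function(records) {
  d <- as.data.frame(records)
  d$age_years <- floor(d$capture_age / 12)
  rhs <- c(if (length(unique(d$sex)) > 1) "factor(sex)",
           if (length(unique(d$age_years)) > 1) "factor(age_years)")
  f <- stats::as.formula(paste("weight ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
  adj <- stats::resid(stats::lm(f, data = d)) + mean(d$weight)
  ym <- tapply(adj, d$capture_year, mean)
  sizes <- as.integer(table(d$capture_year))
  years <- as.integer(names(ym))
  list(slope = weighted_slope(years, as.numeric(ym), sizes),
       years = years, means = as.numeric(ym), sizes = sizes)
}

#' Phased haplotype pool of a GenotypeSet
#'
#' Stacks both haplotypes of every (or a subset of) individual(s) into the
#' haplotypes x SNPs pool used to seed gene-dropping.
#'
#' @param g A phased `GenotypeSet`.
#' @param ids Individuals contributing haplotypes (default all).
#' @return Integer matrix (2 x individuals) x SNPs.
#' @export
haplotype_pool <- function(g, ids = rownames(g$geno)) {
  if (is.null(g$haplotypes)) stop("GenotypeSet carries no phased haplotypes")
  ri <- match(ids, rownames(g$geno))
  rbind(g$haplotypes[[1]][ri, , drop = FALSE],
        g$haplotypes[[2]][ri, , drop = FALSE])
}

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (arguments for [simulate_study()]) or `paths`
#' (named list: `pedigree`, `genotypes`, `phenotypes`, plus
#' `genotype_format`) must be supplied.
#'
#' @param synthetic Named list of [simulate_study()] arguments, or `NULL`.
#' @param paths Named list of input files, or `NULL`.
#' @param year_ranges List of length-2 vectors of birth years for the trend
#'   analyses; `NULL` means one range spanning the gene-drop founder cutoff
#'   to the last cohort.
#' @param prior A [mixture_prior()].
#' @param mcmc_genomic,mcmc_pedigree [mcmc_settings()] for the SNP-effect
#'   model and the animal model.
#' @param drop_cfg A [gene_drop_config()].
#' @param min_cohort_size Minimum cohort size for trend analyses.
#' @param generation_time Mean generation interval (years) for the Haldane
#'   rate, or `NULL` to skip it.
#' @param qc Logical: run [qc_filter()] on the genotypes.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @return A `RunConfig` list.
#' @export
run_config <- function(synthetic = NULL, paths = NULL, year_ranges = NULL,
                       prior = mixture_prior(),
                       mcmc_genomic = mcmc_settings(4000, 1000, 500),
                       mcmc_pedigree = mcmc_settings(4000, 1000, 500),
                       drop_cfg = gene_drop_config(),
                       min_cohort_size = 10, generation_time = NULL,
                       qc = TRUE, seed = 1, outdir = NULL) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("supply exactly one of `synthetic` or `paths`")
  }
  structure(list(synthetic = synthetic, paths = paths,
                 year_ranges = year_ranges, prior = prior,
                 mcmc_genomic = mcmc_genomic, mcmc_pedigree = mcmc_pedigree,
                 drop_cfg = drop_cfg, min_cohort_size = min_cohort_size,
                 generation_time = generation_time, qc = qc,
                 seed = as.integer(seed), outdir = outdir),
            class = "RunConfig")
}

#' Run the full trend-and-drift pipeline
#'
#' Stages: data acquisition (synthetic simulation or file input), phenotype
#' window filter, genotype QC, stage-one phenotype adjustment, SNP-effect
#' model and posterior GEBVs, pedigree animal model and posterior EBVs,
#' posterior trend per year range for both EBV sources, both drift nulls
#' applied to both EBV sources (a 2 x 2 grid of `p_drift` values), the
#' phenotypic trend, and optionally the Haldane rate.
#'
#' @param cfg A [run_config()].
#' @return A `PipelineResult` list; if `cfg$outdir` is set, summary JSON and
#'   per-stage TSVs are written there as a side effect.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  set.seed(cfg$seed)
  seeds <- sample.int(2^31 - 2, 10)

  if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    args$seed <- args$seed %||% seeds[1]
    study <- do.call(simulate_study, args)
    ped <- study$ped
    g <- study$genotypes
    records <- study$records
  } else {
    study <- NULL
    ped <- read_pedigree(cfg$paths$pedigree)
    g <- read_genotypes(cfg$paths$genotypes,
                        format = cfg$paths$genotype_format %||% "matrix")
    records <- utils::read.table(cfg$paths$phenotypes, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  }

  records <- filter_phenotypes(records)
  if (isTRUE(cfg$qc)) g <- qc_filter(g)

  adj <- fit_repeatability_model(records)
  train <- adj$phenotypes[adj$phenotypes$id %in% rownames(g$geno), , drop = FALSE]
  if (nrow(train) == 0) stop("no genotyped, phenotyped individuals to train on")

  mg <- cfg$mcmc_genomic; mg$seed <- as.integer(seeds[2])
  chain <- fit_bayesr(train, g, cfg$prior, mg)
  gebv <- predict_gebv(chain, g, birth_year = ped)

  mp <- cfg$mcmc_pedigree; mp$seed <- as.integer(seeds[3])
  am <- fit_animal_model(records, ped, mcmc = mp,
                         restrict_ids = rownames(g$geno))
  pebv <- am$ebv

  year_ranges <- cfg$year_ranges %||%
    list(c(cfg$drop_cfg$founder_year_cutoff, max(ped$birth_year)))

  pool <- if (!is.null(g$haplotypes)) haplotype_pool(g) else
    stop("gene-dropping needs phased haplotypes in the genotype data")
  map <- g$map
  donor_ids <- rownames(g$geno)

  per_range <- lapply(year_ranges, function(yr) {
    tr_g <- posterior_trend(gebv, yr, cfg$min_cohort_size)
    tr_p <- posterior_trend(pebv, yr, cfg$min_cohort_size)
    dc <- cfg$drop_cfg; dc$seed <- as.integer(seeds[4])
    null_g <- drift_null_genomic(ped, pool, map, chain, dc, yr,
                                 cfg$min_cohort_size, ids = donor_ids)
    # the pedigree null needs as many sigma2_A draws as genomic samples when
    # applied to the genomic trend; recycle evenly if the chains differ
    s2a <- am$varcomp[, "sigma2_A"]
    pick <- function(S) s2a[ceiling(seq_len(S) * length(s2a) / S)]
    null_p_for_g <- drift_null_pedigree(ped, pick(length(tr_g$slopes)),
                                        seed = seeds[5], yr,
                                        cfg$min_cohort_size, ids = donor_ids)
    null_p_for_p <- drift_null_pedigree(ped, pick(length(tr_p$slopes)),
                                        seed = seeds[6], yr,
                                        cfg$min_cohort_size, ids = donor_ids)
    null_g_for_p <- null_g[ceiling(seq_along(tr_p$slopes) *
                                     length(null_g) / length(tr_p$slopes))]
    list(year_range = yr,
         trend_gebv = tr_g, trend_pebv = tr_p,
         drift = list(
           gebv = list(genomic = p_drift(tr_g, null_g),
                       pedigree = p_drift(tr_g, null_p_for_g)),
           pebv = list(genomic = p_drift(tr_p, null_g_for_p),
                       pedigree = p_drift(tr_p, null_p_for_p))),
         haldane = if (!is.null(cfg$generation_time)) {
           haldane_rate(tr_g, mean_trait = mean(records$weight),
                        trait_values_for_sd = mean(records$weight) +
                          rowMeans(gebv$value),
                        generation_time = cfg$generation_time)
         })
  })

  res <- structure(list(config = cfg, study = study, records = records,
                        adjusted = adj, chain = chain, gebv = gebv,
                        animal_model = am, pebv = pebv,
                        phenotypic = phenotypic_trend(records),
                        ranges = per_range, seeds = seeds),
                   class = "PipelineResult")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(res, cfg$outdir)
  res
}

#' Compact summary of a pipeline run
#'
#' @param object A `PipelineResult`.
#' @param ... Unused.
#' @return Nested list of the headline numbers (slopes, credible intervals,
#'   `P_stasis`, the 2 x 2 `p_drift` grid, phenotypic slope, variance
#'   components).
#' @export
#' @method summary PipelineResult
summary.PipelineResult <- function(object, ...) {
  rng <- lapply(object$ranges, function(r) {
    list(year_range = r$year_range,
         gebv_slope = r$trend_gebv$summary$mean,
         gebv_ci95 = r$trend_gebv$summary$ci95,
         gebv_p_stasis = r$trend_gebv$summary$p_stasis,
         pebv_slope = r$trend_pebv$summary$mean,
         pebv_ci95 = r$trend_pebv$summary$ci95,
         pebv_p_stasis = r$trend_pebv$summary$p_stasis,
         p_drift = list(
           gebv_genomic = r$drift$gebv$genomic$p_drift,
           gebv_pedigree = r$drift$gebv$pedigree$p_drift,
           pebv_genomic = r$drift$pebv$genomic$p_drift,
           pebv_pedigree = r$drift$pebv$pedigree$p_drift),
         haldane = if (!is.null(r$haldane)) r$haldane$summary)
  })
  list(phenotypic_slope = object$phenotypic$slope,
       varcomp_stage1 = as.list(object$adjusted$varcomp),
       h2_animal_model = mean(object$animal_model$h2),
       sigma2_A_animal_model = mean(object$animal_model$varcomp[, "sigma2_A"]),
       ranges = rng)
}

#' @export
#' @method print PipelineResult
print.PipelineResult <- function(x, ...) {
  s <- summary(x)
  cat("Pipeline run over", length(s$ranges), "year range(s)\n")
  cat(sprintf("phenotypic slope: %.4f kg/yr\n", s$phenotypic_slope))
  for (r in s$ranges) {
    cat(sprintf("cohorts %d-%d: GEBV %.4f kg/yr (P_stasis %.3f), pedigree EBV %.4f kg/yr (P_stasis %.3f)\n",
                r$year_range[1], r$year_range[2], r$gebv_slope,
                r$gebv_p_stasis, r$pebv_slope, r$pebv_p_stasis))
    cat(sprintf("  p_drift (EBV source x null source): gebv/genomic %.3f, gebv/pedigree %.3f, pebv/genomic %.3f, pebv/pedigree %.3f\n",
                r$p_drift$gebv_genomic, r$p_drift$gebv_pedigree,
                r$p_drift$pebv_genomic, r$p_drift$pebv_pedigree))
  }
  invisible(x)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(summary(res), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_ebv_posterior(res$gebv, file.path(outdir, "gebv_posterior.tsv"))
  write_ebv_posterior(res$pebv, file.path(outdir, "pebv_posterior.tsv"))
  for (k in seq_along(res$ranges)) {
    r <- res$ranges[[k]]
    tag <- paste0(r$year_range[1], "_", r$year_range[2])
    utils::write.table(
      data.frame(sample = seq_along(r$trend_gebv$slopes),
                 gebv_slope = r$trend_gebv$slopes,
                 null_genomic = r$drift$gebv$genomic$null,
                 null_pedigree = r$drift$gebv$pedigree$null),
      file.path(outdir, paste0("slopes_", tag, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' Serialize an EbvPosterior to TSV
#'
#' Columns: `id`, `birth_year`, `training`, then one column per posterior
#' sample (`s1`, `s2`, ...).
#'
#' @param ebv An `EbvPosterior`.
#' @param path Output path.
#' @export
write_ebv_posterior <- function(ebv, path) {
  df <- data.frame(id = ebv$ids, birth_year = ebv$birth_year,
                   training = ebv$training,
                   provenance = ebv$provenance, check.names = FALSE)
  v <- as.data.frame(ebv$value)
  names(v) <- paste0("s", seq_len(ncol(v)))
  utils::write.table(cbind(df, v), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an EbvPosterior written by [write_ebv_posterior()]
#'
#' @param path Input path.
#' @return An `EbvPosterior`.
#' @export
read_ebv_posterior <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  scols <- grep("^s[0-9]+$", names(df))
  v <- as.matrix(df[, scols, drop = FALSE])
  rownames(v) <- df$id
  ebv_posterior(v, birth_year = stats::setNames(df$birth_year, df$id),
                provenance = df$provenance[1], training = df$training)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `prior`,
#' `mcmc_genomic`, `mcmc_pedigree` and `drop_cfg` are given as nested maps
#' of the corresponding constructor arguments.
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    synthetic = y$synthetic,
    paths = y$paths,
    year_ranges = y$year_ranges,
    min_cohort_size = y$min_cohort_size %||% 10,
    generation_time = y$generation_time,
    qc = y$qc %||% TRUE,
    seed = y$seed %||% 1,
    outdir = y$outdir
  )
  if (!is.null(y$prior)) args$prior <- do.call(mixture_prior, y$prior)
  if (!is.null(y$mcmc_genomic)) args$mcmc_genomic <- do.call(mcmc_settings, y$mcmc_genomic)
  if (!is.null(y$mcmc_pedigree)) args$mcmc_pedigree <- do.call(mcmc_settings, y$mcmc_pedigree)
  if (!is.null(y$drop_cfg)) args$drop_cfg <- do.call(gene_drop_config, y$drop_cfg)
  do.call(run_config, args)
}
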
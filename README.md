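# gebvtrend

Detecting microevolutionary change of a quantitative trait in a wild,
pedigreed, genotyped population — and deciding whether the change exceeds
what genetic drift alone could produce.

Long-term individual-based studies (the motivating case is adult August
body weight, in kg, in an unmanaged sheep population followed for ~35
years) often find that a trait's phenotypic mean declines while selection
demonstrably favours larger values. The resolution can be *cryptic
evolution*: breeding values rise while an opposing environmental trend
drags phenotypes down. Demonstrating that requires (i) posterior
distributions of individual breeding values, (ii) trend inference that
carries their uncertainty, and (iii) an explicit drift null.

## The model chain

1. **Phenotype adjustment** (stage one): REML fit of
   `weight ~ sex + age + (1|id) + (1|birth year) + (1|capture year)`;
   the individual-identity BLUP (optionally deregressed by its
   reliability) is the working phenotype.
2. **Genomic prediction**: a four-component normal-mixture model of SNP
   effects `beta_j` — a point mass at zero plus components with variances
   `(1e-4, 1e-3, 1e-2)` of a reference variance — sampled by Gibbs
   (component indicators, effects, Dirichlet mixture proportions `pi`,
   scaled-inverse-chi-squared variances, intercept). Posterior GEBVs are
   `u_i^(s) = sum_j (g_ij - 2 p_j) beta_j^(s)` for every genotyped
   individual, phenotyped or not. A leave-one-cohort-out variant and
   k-fold cross-validated accuracy are included.
3. **Pedigree animal model**: the same trait on raw repeated measures with
   an additive effect structured by the numerator relationship matrix
   (sparse `A^{-1}` via Henderson's rules with Meuwissen-Luo inbreeding),
   Gibbs-sampled, giving posterior pedigree EBVs for comparison.
4. **Trend inference**: per posterior sample, the size-weighted regression
   of cohort mean breeding value on birth year
   `b = sum w (x - xbar_w)(y - ybar_w) / sum w (x - xbar_w)^2`;
   summaries are the posterior mean slope, percentile 95% credible
   interval, `P(stasis) = P(b <= 0)`, and a Haldane-rate conversion
   (log-scale change per generation in trait SD units).
5. **Drift nulls**: (a) gene-dropping of phased haplotypes through the
   pedigree with recombination (template switching at each interval's
   recombination fraction, 0.5 across chromosomes; donors replace missing
   parents), converted to breeding values with a *different posterior
   sample of SNP effects per simulation*; (b) classical midparent
   breeding-value dropping from posterior samples of `sigma2_A`.
   `p_drift` is the proportion of paired simulations whose null slope
   strictly exceeds the real slope.

A forward simulator (`simulate_study()`, `study_design()`) co-simulates
demography, inheritance and phenotypes — including a viability-selection
regime masked by an environmental decline — so the whole chain is testable
without external data.

## Worked example

```r
library(gebvtrend)

st <- do.call(simulate_study, c(study_design("cryptic"), list(seed = 1)))
adj <- fit_repeatability_model(filter_phenotypes(st$records), deregress = TRUE)
g <- qc_filter(st$genotypes)
train <- adj$phenotypes[adj$phenotypes$id %in% rownames(g$geno), ]
chain <- fit_bayesr(train, g, mixture_prior(reference = "genetic"),
                    mcmc_settings(4000, 1000, 500, seed = 2))
gebv <- predict_gebv(chain, g, birth_year = st$ped)
posterior_trend(gebv, min_cohort_size = 10)
```

On one realization of the cryptic design (seed 1 of
`scripts/acceptance.R`, ~2300 individuals over 15 cohorts), the pipeline
prints:

```
gebv_trend_slope     0.0277   # kg/yr; the simulator's true slope was 0.0307
gebv_p_stasis        0.0000   # no posterior mass on stasis
phenotypic_slope    -0.2458   # kg/yr: weight *declines* while genes improve
p_drift_genomic_gebv 0.0100   # drift unlikely to explain the genetic trend
cv_accuracy          0.7659   # 5-fold held-out GEBV accuracy
h2_animal_model      0.2816   # pedigree-model heritability
haldane_rate         0.0677   # trait SDs per generation (generation time 4 yr)
```

Read together: phenotypes fell by ~0.25 kg/yr, yet breeding values rose by
~0.028 kg/yr, the 95% credible interval excludes zero, and only 1% of
gene-dropped drift simulations produced a steeper genetic trend — cryptic
microevolution, correctly recovered.

The `analysis/` directory runs the same workflow as numbered drivers
(`01_simulate_study.R` … `07_calibration.R`), writing tables under
`results/analysis/`.

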
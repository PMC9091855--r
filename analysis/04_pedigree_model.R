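#!/usr/bin/env Rscript
# Bayesian pedigree animal model on the raw repeated measures; posterior
# pedigree EBVs restricted to the genotyped individuals for comparability.
suppressMessages(library(gebvtrend))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/analysis"
st <- readRDS(file.path(out, "study.rds"))
s1 <- readRDS(file.path(out, "stage1.rds"))

am <- fit_animal_model(s1$records, st$ped,
                       mcmc = mcmc_settings(4000, 1000, 500, seed = seed),
                       restrict_ids = rownames(s1$g$geno))
print(am)
write_ebv_posterior(am$ebv, file.path(out, "pebv_posterior.tsv"))
saveRDS(am, file.path(out, "animal_model.rds"))
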
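#!/usr/bin/env Rscript
# SNP-effect mixture model on the adjusted phenotypes and posterior genomic
# breeding values for every genotyped individual; cross-validated accuracy.
suppressMessages(library(gebvtrend))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/analysis"
st <- readRDS(file.path(out, "study.rds"))
s1 <- readRDS(file.path(out, "stage1.rds"))

train <- s1$adj$phenotypes[s1$adj$phenotypes$id %in% rownames(s1$g$geno), ]
prior <- mixture_prior(reference = "genetic")
chain <- fit_bayesr(train, s1$g, prior, mcmc_settings(4000, 1000, 500, seed = seed))
print(chain)
gebv <- predict_gebv(chain, s1$g, birth_year = st$ped)
write_ebv_posterior(gebv, file.path(out, "gebv_posterior.tsv"))
saveRDS(list(chain = chain, gebv = gebv), file.path(out, "genomic.rds"))

acc <- cv_accuracy(train, s1$g, k_folds = 5, prior = prior,
                   mcmc = mcmc_settings(2000, 500, 150, seed = seed), seed = seed)
cat(sprintf("Cross-validated accuracy (5-fold): %.3f\n", as.numeric(acc)))
cat(sprintf("Accuracy against simulated true breeding values: %.3f\n",
            cor(rowMeans(gebv$value), st$bv[gebv$ids])))
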
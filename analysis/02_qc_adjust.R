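#!/usr/bin/env Rscript
# Quality control and stage-one phenotype adjustment: filter August adult
# records, run genotype QC, fit the repeatability mixed model and extract
# deregressed individual effects as the working phenotype.
suppressMessages(library(gebvtrend))
out <- "results/analysis"
st <- readRDS(file.path(out, "study.rds"))

records <- filter_phenotypes(st$records)
g <- qc_filter(st$genotypes)
print(attr(g, "qc_report"))

adj <- fit_repeatability_model(records, deregress = TRUE)
print(adj)
write_adjusted_phenotypes(adj, file.path(out, "adjusted_phenotypes.tsv"))
saveRDS(list(records = records, g = g, adj = adj),
        file.path(out, "stage1.rds"))
cat(sprintf("%d genotyped-and-phenotyped individuals available for training.\n",
            sum(adj$phenotypes$id %in% rownames(g$geno))))
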
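#!/usr/bin/env Rscript
# Ancestry PCA on the curated genotype matrix (covariates of every scan
# model) and the environmental PCA used for the robustness check.

library(mtclimscan)

outdir <- "results/ancestry"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

vcf <- read_vcf("results/curated/variants.vcf")
climate <- read_climate_table("results/data/climate.csv")

pcs <- genotype_pca(vcf$genotypes, n_components = 4)
cat("Genotype PCA variance fractions:",
    paste(signif(pcs$var_explained, 3), collapse = " "), "\n")
write.csv(data.frame(individual_id = pcs$ids, pcs$scores),
          file.path(outdir, "pca_scores.csv"), row.names = FALSE)

# environmental PC1 from the bioclimatic columns (excludes latitude itself)
env_cols <- c("country", climate_predictor_names()$paleo)
env <- environmental_pca(climate[, env_cols], n_components = 1)
cat("Environmental PC1 explains", signif(env$var_explained[1], 3),
    "of bioclimatic variance.\n")
write.csv(data.frame(country = env$ids, env_pc1 = env$scores[, 1]),
          file.path(outdir, "env_pca.csv"), row.names = FALSE)
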
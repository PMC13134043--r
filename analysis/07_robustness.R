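#!/usr/bin/env Rscript
# Robustness re-run: repeat the latitude/precipitation scan after excluding
# a block of countries (the analogue of dropping the Americas, Australia and
# New Zealand), and compare candidate sets.

library(mtclimscan)

outdir <- "results/robustness"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

vcf <- read_vcf("results/curated/variants.vcf")
countries <- read_country_table("results/curated/countries_retained.csv")
climate <- read_climate_table("results/data/climate.csv")

# exclude the three largest retained countries as the stress case
sizes <- sort(table(countries[vcf$genotypes$ids]), decreasing = TRUE)
excluded <- names(sizes)[1:3]
cat("Excluding countries:", paste(excluded, collapse = ", "),
    sprintf("(%d of %d individuals)\n", sum(sizes[excluded]), sum(sizes)))

ex <- exclude_regions(vcf$genotypes, countries, excluded)
pcs <- genotype_pca(ex$genotypes, 4)
sc <- run_latprecip_scan(ex$genotypes, pcs, ex$countries, climate)
print(sc)
write.csv(sc$table, file.path(outdir, "scan_latprecip_excluded.csv"),
          row.names = FALSE)

full <- read.csv("results/scan/scan_latprecip.csv")
both <- merge(full[, c("pos", "candidate")],
              sc$table[, c("pos", "candidate")], by = "pos",
              suffixes = c("_full", "_excluded"))
cat(sprintf("Candidates: %d (full) vs %d (excluded); %d shared.\n",
            sum(both$candidate_full), sum(both$candidate_excluded),
            sum(both$candidate_full & both$candidate_excluded)))
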
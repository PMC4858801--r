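#!/usr/bin/env Rscript
# Stage 4: recombination landscape. 1-Mb crossover probabilities per sex
# with the boundary-splitting allocation, the distance-to-telomere model
# (AIC over candidate transforms, sex interaction, SNP count and GC
# covariates), and the broad-scale chromosome-length regressions.
#
# GC content per bin is an input table in real analyses; here a synthetic
# GC table (labelled as such) provides the covariate.

suppressPackageStartupMessages(library(pedrecomb))

cfg <- sim_config_validation(seed = 20240915)   # chromosome lengths
lens <- setNames(cfg$chromosome_lengths_bp, seq_along(cfg$chromosome_lengths_bp))

iv_m <- as.data.frame(data.table::fread("results/intervals_male.tsv"))
iv_f <- as.data.frame(data.table::fread("results/intervals_female.tsv"))

## synthetic GC covariate (GC rises towards chromosome ends, as in many
## mammalian genomes)
set.seed(20240915)
gc_for <- function(bins) {
  within(bins, gc_percent <- 44 + 3 * exp(-dist_telomere_mb / 15) +
           rnorm(nrow(bins), 0, 1))
}
bins_m <- gc_for(bin_crossover_probability(iv_m, lens))
bins_f <- gc_for(bin_crossover_probability(iv_f, lens))
bins_f$gc_percent <- bins_m$gc_percent     # GC is a property of the bin
data.table::fwrite(bins_m, "results/bins_male.tsv", sep = "\t")
data.table::fwrite(bins_f, "results/bins_female.tsv", sep = "\t")

cons_m <- abs(sum(bins_m$prob) - sum(iv_m$r, na.rm = TRUE))
message(sprintf("conservation check (male map): |sum bins - sum r| = %.2e", cons_m))

tm <- fit_telomere_model(bins_m, bins_f)
message(sprintf("telomere-distance transform chosen by AIC: %s", tm$chosen))
message(paste(capture.output(print(round(sort(tm$aic - min(tm$aic)), 1))),
              collapse = "\n"))

nd <- data.frame(dist_telomere_mb = c(2, 10, 25, 50), n_snps = 15, gc_percent = 45)
diff_mf <- predict(tm$best, cbind(nd, sex = "M")) -
  predict(tm$best, cbind(nd, sex = "F"))
message(paste(sprintf("male - female crossover probability at %2g Mb from telomere: %+.4f",
                      nd$dist_telomere_mb, diff_mf), collapse = "\n"))

lmap <- as.data.frame(data.table::fread("results/linkage_map.tsv"))
br <- broadscale_regressions(chromosome_map_lengths(lmap, lens))
data.table::fwrite(br$summary, "results/broadscale_summary.tsv", sep = "\t")
message(paste(capture.output(print(br$summary, digits = 3)), collapse = "\n"))
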
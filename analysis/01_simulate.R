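#!/usr/bin/env Rscript
# Stage 1: simulate the two synthetic datasets the analysis runs on.
#
# (a) "mapping" dataset: a 3-generation pedigree (~200 phase-informative
#     gametes) genotyped at array-scale SNP density. Used for crossover
#     detection, linkage maps and the recombination landscape.
# (b) "genetics" dataset: a larger pedigree (~1,600 gametes from 400 focal
#     individuals) at genome-wide-association marker density, with a
#     female-limited major QTL for autosomal crossover count (ACC) of
#     +2.455 crossovers per copy (homozygote difference 4.91) at frequency
#     0.27 on chromosome 6, on top of a polygenic background tuned to
#     h2 = 0.145 and V_P = 29.56.
#
# Outputs under results/data/.

suppressPackageStartupMessages(library(pedrecomb))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

seed <- 20240915

## (a) mapping dataset -------------------------------------------------------
# litter size raised so ~416 gametes are phase-informative: two-point
# sex-specific interval estimates need all the joint coverage they can get
cfg_map <- sim_config_validation(seed = seed, offspring_per_pair = c(4, 4))
ped_map <- simulate_pedigree(cfg_map)
gd_map <- gene_drop(ped_map, cfg_map)
write_pedigree(ped_map, "results/data/mapping_pedigree.tsv")
write_genotypes_tsv(gd_map$panel, "results/data/mapping")
data.table::fwrite(gd_map$truth, "results/data/mapping_truth.tsv", sep = "\t")
data.table::fwrite(cbind(gamete = rownames(gd_map$truth_counts),
                         as.data.frame(gd_map$truth_counts)),
                   "results/data/mapping_truth_counts.tsv", sep = "\t")
message(sprintf("mapping dataset: %d individuals, %d SNPs, %d gametes (mean true ACC %.1f)",
                nrow(ped_map), ncol(gd_map$panel$geno), nrow(gd_map$truth),
                mean(gd_map$truth$acc_true)))

## (b) genetics dataset ------------------------------------------------------
cfg_gen <- sim_config(seed = seed + 1, n_founders = 400,
                      offspring_per_pair = c(2, 4), interference_nu = 8,
                      qtl_spec = list(chr = 6, snp_index = 10, effect = 2.455,
                                      sex = "F", freq = 0.27))
ped_gen <- simulate_pedigree(cfg_gen)
gd_gen <- gene_drop(ped_gen, cfg_gen)
write_pedigree(ped_gen, "results/data/genetics_pedigree.tsv")
write_genotypes_tsv(gd_gen$panel, "results/data/genetics")
write_plink(gd_gen$panel, "results/data/genetics", pedigree = ped_gen)
data.table::fwrite(gd_gen$truth, "results/data/genetics_truth.tsv", sep = "\t")
data.table::fwrite(cbind(gamete = rownames(gd_gen$truth_counts),
                         as.data.frame(gd_gen$truth_counts)),
                   "results/data/genetics_truth_counts.tsv", sep = "\t")

gen <- setNames(ped_gen$generation, as.character(ped_gen$id))
tr <- gd_gen$truth[gen[gd_gen$truth$parent] == 1, ]
message(sprintf("genetics dataset: %d SNPs, %d gametes from %d focal individuals",
                ncol(gd_gen$panel$geno), nrow(tr), length(unique(tr$parent))))
message(sprintf("  per-sex mean (var) of true ACC: M %.1f (%.1f), F %.1f (%.1f)",
                mean(tr$acc_true[tr$parent_sex == "M"]),
                var(tr$acc_true[tr$parent_sex == "M"]),
                mean(tr$acc_true[tr$parent_sex == "F"]),
                var(tr$acc_true[tr$parent_sex == "F"])))
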
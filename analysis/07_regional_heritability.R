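#!/usr/bin/env Rscript
# Stage 7: regional heritability scan. Additive variance is partitioned
# into a 20-SNP sliding-window GRM plus a rest-of-genome GRM; each window
# is tested by LRT with the overlap-aware Bonferroni threshold
# (alpha / (n_windows / 2)). The full scan is run on the QTL chromosome
# and one control chromosome; the threshold uses the genome-wide window
# count.

suppressPackageStartupMessages(library(pedrecomb))

ped <- read_pedigree("results/data/genetics_pedigree.tsv")
panel <- read_genotypes_tsv("results/data/genetics")
truth <- as.data.frame(data.table::fread("results/data/genetics_truth.tsv"))

truth$parent <- as.character(truth$parent)
gen <- setNames(ped$generation, as.character(ped$id))
tr <- truth[gen[truth$parent] == 1 & truth$parent_sex == "F", ]
acc <- data.frame(gamete = tr$gamete, fid = tr$parent, acc = tr$acc_true)

w_all <- make_windows(panel, size = 20)
thr <- 0.05 / (nrow(w_all) / 2)
w_scan <- w_all[w_all$chr %in% c(6, 12), ]
message(sprintf("scanning %d of %d windows (chromosomes 6 and 12); genome-wide threshold %.2e",
                nrow(w_scan), nrow(w_all), thr))

sc <- regional_scan(panel, acc, size = 20, windows = w_scan)
sc$scan$significant <- !is.na(sc$scan$p) & sc$scan$p < thr
data.table::fwrite(sc$scan, "results/regional_scan_female.tsv", sep = "\t")

hits <- sc$scan[sc$scan$significant, ]
if (nrow(hits)) {
  for (i in seq_len(nrow(hits)))
    message(sprintf("significant window: chr %d @ %.1f Mb, regional share %.3f (SE %.3f), p = %.2e",
                    hits$chr[i], hits$median_bp[i] / 1e6, hits$h2_regional[i],
                    hits$h2_regional_se[i], hits$p[i]))
} else message("no window passed the threshold")
message(sprintf("boundary (masked) windows: %d of %d",
                sum(sc$scan$boundary), nrow(sc$scan)))
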
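#!/usr/bin/env Rscript
# Stage 8: haplotype sharing around a focal SNP between a focal and a
# reference population. Both populations are simulated from a shared pool
# of ancestral haplotypes (block LD), so short-range sharing exists by
# construction; cores of 6 SNPs adjacent to the focal SNP that perfectly
# tag one focal allele are extracted, and the distance to the first
# downstream mismatch is recorded over all cross-population carrier pairs.

suppressPackageStartupMessages(library(pedrecomb))
set.seed(20240915)

# one 4-Mb region, 58 SNPs, as a subtelomeric extract would provide
m <- 58
bp <- sort(sample.int(4e6, m))
K <- 8                                     # ancestral haplotype pool
anc <- matrix(rbinom(K * m, 1, runif(m, 0.2, 0.8)[rep(1:m, each = K)]),
              nrow = K)
draw_pop <- function(n, label) {
  H <- t(replicate(n, {
    blocks <- rep(1:ceiling(m / 12), each = 12)[1:m]
    h <- integer(m)
    for (b in unique(blocks)) {
      cols <- which(blocks == b)
      h[cols] <- anc[sample.int(K, 1), cols]
    }
    # sprinkle of recent mutation/genotype diversity
    flip <- runif(m) < 0.02
    h[flip] <- 1L - h[flip]
    h
  }))
  haplotype_set(H, bp, label)
}
focal_pop <- draw_pop(60, "focal")
ref_pop <- draw_pop(40, "reference")

focal_idx <- 40
cores <- find_core_haplotypes(focal_pop, focal_idx, core_length = 6)
message(sprintf("core haplotypes perfectly tagging the focal SNP: %d (alleles: %s)",
                nrow(cores), paste(cores$tagged_allele, collapse = "/")))

rows <- list()
for (i in seq_len(nrow(cores))) {
  hs <- haplotype_sharing_length(cores[i, ], focal_pop, ref_pop)
  rows[[i]] <- data.frame(core = cores$core[i],
                          tagged_allele = cores$tagged_allele[i],
                          n_pairs = hs$n_pairs, n_censored = hs$n_censored,
                          mean_bp = hs$mean_bp, sd_bp = hs$sd_bp,
                          mean_bp_all = hs$mean_bp_all)
  if (hs$n_pairs > 0)
    message(sprintf("core %s (allele %d): mean sharing %.0f bp over %d pairs (%d censored at region end)",
                    cores$core[i], cores$tagged_allele[i],
                    hs$mean_bp_all, hs$n_pairs, hs$n_censored))
}
data.table::fwrite(do.call(rbind, rows), "results/haplotype_sharing.tsv",
                   sep = "\t")
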
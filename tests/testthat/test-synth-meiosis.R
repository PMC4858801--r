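# Gene-dropping meiosis simulator.

test_that("pedigree construction produces the requested shape", {
  cfg <- sim_config(n_founders = 4, n_generations = 2,
                    offspring_per_pair = 2, offspring_dist = "fixed", seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 8L)
  off <- ped[ped$generation == 1, ]
  expect_equal(nrow(off), 4L)
  expect_true(all(!is.na(off$sire) & !is.na(off$dam)))
  expect_true(all(off$sire %in% ped$id & off$dam %in% ped$id))

  founders_only <- simulate_pedigree(sim_config(n_founders = 6, n_generations = 1, seed = 2))
  expect_equal(nrow(founders_only), 6L)
  expect_true(all(is.na(founders_only$sire)))

  # default config: individuals usable as FIDs exist
  cfg3 <- sim_config(seed = 3)
  ped3 <- simulate_pedigree(cfg3)
  subp <- build_subpedigrees(ped3, ped3$id)
  expect_gt(nrow(subp), 0)
})

test_that("pedigree validation rejects cycles and sex-inconsistent parents", {
  bad <- data.frame(id = c(1, 2), sire = c(2, 1), dam = c(NA, NA),
                    sex = c("M", "M"))
  expect_error(validate_pedigree(bad), "ancestor")
  bad2 <- data.frame(id = c(1, 2), sire = c(NA, 1), dam = c(NA, NA),
                     sex = c("F", "M"))
  expect_error(validate_pedigree(bad2), "sire")
})

test_that("crossover counts are Poisson at nu = 1 without obligate crossing over", {
  set.seed(10)
  maps <- list(chrom_map_nodes(1e8, 120),
               chrom_map_nodes(0.8e8, 90))
  n <- 5000
  counts <- t(vapply(seq_len(n), function(i)
    sim_meiosis(maps, t = 1, obligate = FALSE, nu = 1)$counts, integer(2)))
  expect_lt(abs(mean(rowSums(counts)) - 2.1), 3 * sqrt(2.1 / n))
  # chi-square goodness of fit per chromosome, alpha = 0.01
  for (j in 1:2) {
    lambda <- maps[[j]]$total_cm / 100
    x <- counts[, j]
    ks <- 0:max(x)
    p <- dpois(ks, lambda); p[length(p)] <- 1 - ppois(max(x) - 1, lambda)
    obs <- tabulate(x + 1L, nbins = length(ks))
    pool <- p * n >= 5
    obs2 <- c(obs[pool], sum(obs[!pool]))
    p2 <- c(p[pool], sum(p[!pool]))
    stat <- sum((obs2 - n * p2)^2 / (n * p2))
    expect_lt(stat, qchisq(0.99, df = length(obs2) - 1))
  }
})

test_that("obligate mode guarantees a crossover and shifts the mean accordingly", {
  set.seed(11)
  maps <- list(chrom_map_nodes(1e8, 150))
  counts <- vapply(1:2000, function(i)
    sim_meiosis(maps, t = 1, obligate = TRUE, nu = 1)$counts, integer(1))
  expect_true(all(counts >= 1))
  expect_lt(abs(mean(counts) - 1.5), 3 * sqrt(0.5 / 2000))
})

test_that("interference makes inter-crossover spacing more regular", {
  set.seed(12)
  maps <- list(chrom_map_nodes(3e8, 300))
  spacing <- function(nu) {
    unlist(lapply(1:800, function(i) {
      p <- sim_meiosis(maps, t = 1, obligate = FALSE, nu = nu)$positions_bp[[1]]
      if (length(p) >= 2) diff(p) else numeric(0)
    }))
  }
  s1 <- spacing(1); s8 <- spacing(8)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(s1), cv(s8) * 1.5)
})

test_that("gene dropping conserves founder alleles and records true crossovers", {
  set.seed(13)
  cfg <- sim_config(seed = 13, n_founders = 8, offspring_per_pair = c(2, 2),
                    snp_density = 0.3, n_generations = 3)
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg, track_founders = TRUE)
  # every allele traces to the founder haplotype its label names
  H1 <- gd$haplotypes$H1; H2 <- gd$haplotypes$H2
  L1 <- gd$founder_labels$L1
  founders <- gd$founder_rows
  FH <- rbind(H1[founders, ], H2[founders, ])
  lab_row <- function(lab) ifelse(lab %% 2L == 1L, (lab + 1L) %/% 2L,
                                  length(founders) + lab %/% 2L)
  idx <- sample(length(L1), 2000)
  rc <- arrayInd(idx, dim(L1))
  expect_true(all(H1[idx] == FH[cbind(lab_row(L1[idx]), rc[, 2])]))
  # truth bookkeeping: total equals per-chromosome sums, positions increase
  expect_equal(gd$truth$acc_true, unname(rowSums(gd$truth_counts)))
  for (g in sample(names(gd$truth_positions), 5)) {
    for (p in gd$truth_positions[[g]]) {
      if (length(p) > 1) expect_true(all(diff(p) > 0))
    }
  }
  # genotypes are the sum of the two haplotypes (no error configured)
  expect_equal(unname(gd$panel$geno), unname(H1 + H2))
})

test_that("a fully homozygous panel yields no phase information", {
  cfg <- sim_config(seed = 14, n_founders = 8, offspring_per_pair = c(2, 2),
                    snp_density = 0.1, founder_allele_freqs = 1)
  ped <- simulate_pedigree(cfg)
  expect_warning(gd <- gene_drop(ped, cfg), "monomorphic")
  subp <- build_subpedigrees(ped, ped$id)
  ph <- phase_gametes(subp, gd$panel)
  expect_equal(nrow(ph), 0L)
})

test_that("a female-limited QTL shifts female ACC by its homozygote difference", {
  set.seed(15)
  cfg <- sim_config(seed = 15, n_founders = 60, offspring_per_pair = c(4, 3),
                    snp_density = 0.1, maf_range = c(0.5, 0.5),
                    qtl_spec = list(chr = 1, snp_index = 3, effect = 2.455,
                                    sex = "F"))
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg)
  qtl_col <- which(gd$panel$map$chr == 1)[3]
  dose <- gd$panel$geno[gd$truth$parent, qtl_col]
  tr <- gd$truth
  f0 <- tr$parent_sex == "F" & dose == 0
  f2 <- tr$parent_sex == "F" & dose == 2
  diff_f <- mean(tr$acc_true[f2]) - mean(tr$acc_true[f0])
  se <- sqrt(var(tr$acc_true[f2]) / sum(f2) + var(tr$acc_true[f0]) / sum(f0))
  expect_lt(abs(diff_f - 4.91), 2 * se)
  # males unaffected
  m0 <- tr$parent_sex == "M" & dose == 0
  m2 <- tr$parent_sex == "M" & dose == 2
  diff_m <- mean(tr$acc_true[m2]) - mean(tr$acc_true[m0])
  se_m <- sqrt(var(tr$acc_true[m2]) / sum(m2) + var(tr$acc_true[m0]) / sum(m0))
  expect_lt(abs(diff_m), 3 * se_m)
})

test_that("gene drop is bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 16, n_founders = 8, offspring_per_pair = c(2, 2),
                    snp_density = 0.2)
  ped1 <- simulate_pedigree(cfg); gd1 <- gene_drop(ped1, cfg)
  ped2 <- simulate_pedigree(cfg); gd2 <- gene_drop(ped2, cfg)
  expect_identical(ped1, ped2)
  expect_identical(gd1$panel$geno, gd2$panel$geno)
  expect_identical(gd1$truth, gd2$truth)
})

test_that("validation harness is deterministic and degrades with marker thinning", {
  cfg_lo <- sim_config_validation(seed = 17, n_founders = 16,
                                  offspring_per_pair = c(3, 2), snp_density = 1)
  vr_lo_a <- validation_run(cfg_lo, n_simulations = 2)
  vr_lo_b <- validation_run(cfg_lo, n_simulations = 2)
  expect_identical(vr_lo_a$per_simulation, vr_lo_b$per_simulation)

  cfg_hi <- sim_config_validation(seed = 17, n_founders = 16,
                                  offspring_per_pair = c(3, 2), snp_density = 8)
  vr_hi <- validation_run(cfg_hi, n_simulations = 2)
  expect_gt(mean(vr_hi$per_simulation$adj_r_squared),
            mean(vr_lo_a$per_simulation$adj_r_squared))
})
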
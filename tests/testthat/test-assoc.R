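# SNP variance, effective tests, genomic control and mixed-model GWAS.

test_that("V_SNP formula: symmetric additive case and domain checks", {
  v <- snp_variance(0.5, 0.5, effect_AB = -1, effect_BB = -2)
  expect_equal(v$V_SNP, 0.5)
  expect_equal(v$d, 0)
  expect_error(snp_variance(0.6, 0.5, 1, 2), "p \\+ q")
  expect_error(snp_variance(1, 0, 1, 2), "frequency")
  v2 <- snp_variance(0.7, 0.3, -1.5, -3, V_A_without_snp = 4)
  expect_equal(v2$prop_VA, v2$V_SNP / (v2$V_SNP + 4))
})

test_that("V_SNP equals the Hardy-Weinberg additive variance by brute force", {
  set.seed(41)
  for (i in 1:25) {
    q <- runif(1, 0.05, 0.95)          # allele B frequency
    eAB <- rnorm(1, 0, 2); eBB <- rnorm(1, 0, 2)
    v <- snp_variance(1 - q, q, eAB, eBB)
    # oracle: weighted regression of class means on dosage under HW weights;
    # the additive variance is the variance of the fitted values
    w <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    mu <- c(0, eAB, eBB)
    x <- c(0, 1, 2)
    fit <- lm(mu ~ x, weights = w)
    fitted_dev <- fitted(fit) - sum(w * fitted(fit))
    V_add <- sum(w * fitted_dev^2)
    expect_equal(v$V_SNP, V_add, tolerance = 1e-12)
  }
})

test_that("effective tests: independence, perfect LD and relabeling invariance", {
  # two exactly uncorrelated SNPs -> n_eff = 2
  map <- data.frame(snp = c("a", "b"), chr = 1L, bp = c(1e5, 2e5))
  G <- matrix(c(0L, 0L, 2L, 2L,
                0L, 2L, 0L, 2L), ncol = 2,
              dimnames = list(paste0("i", 1:4), map$snp))
  et <- effective_tests(genotype_panel(map, G))
  expect_equal(et$n_eff, 2)

  # 50 perfectly correlated SNPs -> n_eff = 1
  m <- 50
  map2 <- data.frame(snp = sprintf("s%d", 1:m), chr = 1L, bp = 1:m * 1e5)
  x <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  G2 <- matrix(rep(x, m), ncol = m, dimnames = list(paste0("j", 1:8), map2$snp))
  et2 <- effective_tests(genotype_panel(map2, G2))
  expect_equal(et2$n_eff, 1)

  # allele relabeling (2 - x) leaves contributions unchanged
  set.seed(42)
  G3 <- sapply(1:30, function(j) rbinom(40, 2, 0.4))
  rownames(G3) <- paste0("k", 1:40)
  map3 <- data.frame(snp = sprintf("r%d", 1:30), chr = 1L, bp = 1:30 * 1e5)
  et3a <- effective_tests(genotype_panel(map3, G3))
  G3b <- G3; G3b[, 7] <- 2L - G3b[, 7]
  et3b <- effective_tests(genotype_panel(map3, G3b))
  expect_equal(et3a$n_eff, et3b$n_eff, tolerance = 1e-12)
})

test_that("genomic-control lambda is calibrated and maps mixed df correctly", {
  # statistics at the exact null median give lambda = 1
  chi2 <- rep(qchisq(0.5, 2), 101)
  expect_equal(genomic_lambda(chi2, rep(2, 101)), 1)
  chi1 <- rep(qchisq(0.5, 1), 101)
  expect_equal(genomic_lambda(chi1, rep(1, 101)), 1)
  expect_equal(genomic_lambda(c(chi2, chi1), c(rep(2, 101), rep(1, 101))), 1)
})

test_that("Wald test with variance fixed at zero additive equals OLS F x df", {
  set.seed(43)
  n <- 60
  ids <- paste0("w", 1:n)
  g <- sample(0:2, n, replace = TRUE)
  y <- 3 + 0.8 * (g == 1) + 1.6 * (g == 2) + rnorm(n)
  map <- data.frame(snp = "s1", chr = 1L, bp = 1e5)
  panel <- genotype_panel(map, matrix(as.integer(g), ncol = 1,
                                      dimnames = list(ids, "s1")))
  acc <- data.frame(gamete = ids, fid = ids, acc = y, sex = "F", chr_1 = 0L)
  gw <- run_gwas(acc, panel, relationship = NULL, stratum = "all",
                 method = "refit", pe = FALSE, window = 5)
  ols <- lm(y ~ factor(g))
  Ftab <- anova(ols)
  expect_equal(gw$records$chi2, Ftab[1, "F value"] * 2, tolerance = 1e-6)
  expect_equal(gw$records$effect_AB, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(gw$records$effect_BB, unname(coef(ols)[3]), tolerance = 1e-6)
})

test_that("GWAS finds a planted individual-level QTL and respects strata", {
  set.seed(44)
  sim <- small_sim(seed = 44, snp_density = 0.15, n_founders = 60,
                   offspring_per_pair = c(4, 3), maf_range = c(0.35, 0.5),
                   qtl_spec = list(chr = 2, snp_index = 5, effect = 4,
                                   sex = "F"))
  gd <- sim$gd
  tr <- gd$truth
  acc <- data.frame(gamete = tr$gamete, fid = tr$parent, acc = tr$acc_true,
                    sex = tr$parent_sex, stringsAsFactors = FALSE)
  for (cc in 1:26) acc[[paste0("chr_", cc)]] <- gd$truth_counts[, cc]
  nrm <- pedigree_nrm(sim$ped)
  qtl_snp <- gd$panel$map$snp[which(gd$panel$map$chr == 2)[5]]

  gw_f <- run_gwas(acc, gd$panel, nrm, stratum = "female")
  top_f <- gw_f$records[which.min(gw_f$records$p), ]
  expect_equal(top_f$snp, qtl_snp)

  gw_m <- run_gwas(acc, gd$panel, nrm, stratum = "male")
  p_m <- gw_m$records$p[gw_m$records$snp == qtl_snp]
  expect_gt(p_m, gw_m$threshold)

  # trans mode: the QTL acts genome-wide, so excluding its own chromosome
  # leaves the association intact
  gw_t <- run_gwas(acc, gd$panel, nrm, stratum = "female", trans = TRUE)
  p_trans <- gw_t$records$p[gw_t$records$snp == qtl_snp]
  expect_lt(p_trans, 0.05)

  # lambda correction is a no-op when lambda <= 1
  if (gw_f$lambda <= 1) expect_equal(gw_f$records$p, gw_f$records$p_corrected)
})

test_that("significance threshold is alpha over the effective test count", {
  expect_equal(significance_threshold(100, 0.05), 5e-4)
  expect_equal(significance_threshold(22273.61, 0.05), 0.05 / 22273.61)
})
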
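# Bin-level crossover probabilities and landscape regressions.

test_that("boundary-straddling intervals split by the base-pair allocation rule", {
  iv <- data.frame(chr = 1L, left_snp = "a", right_snp = "b",
                   left_bp = 0.8e6, right_bp = 1.2e6, r = 0.01)
  bins <- bin_crossover_probability(iv, chromosome_lengths_bp = c(`1` = 2e6))
  expect_equal(bins$prob[1], 0.01 * 200000 / 400000)
  expect_equal(bins$prob[2], 0.005)
  # wholly contained interval
  iv2 <- data.frame(chr = 1L, left_snp = "a", right_snp = "b",
                    left_bp = 0.1e6, right_bp = 0.4e6, r = 0.02)
  bins2 <- bin_crossover_probability(iv2, c(`1` = 2e6))
  expect_equal(bins2$prob, c(0.02, 0))
})

test_that("bin probabilities conserve the chromosome total exactly", {
  set.seed(51)
  bp <- sort(sample.int(60e6, 80))
  iv <- data.frame(chr = 2L, left_snp = head(sprintf("s%d", 1:80), -1),
                   right_snp = sprintf("s%d", 2:80),
                   left_bp = head(bp, -1), right_bp = bp[-1],
                   r = runif(79, 0, 0.02))
  # a multi-bin spanning interval triggers the proportional extension
  iv$r[40] <- 0.05
  iv$right_bp[40] <- iv$left_bp[40] + 3.5e6
  iv$left_bp[41:79] <- pmax(iv$left_bp[41:79], iv$right_bp[40])
  iv$right_bp[41:79] <- pmax(iv$right_bp[41:79], iv$left_bp[41:79] + 1)
  bins <- suppressWarnings(bin_crossover_probability(iv, c(`2` = 60e6)))
  expect_equal(sum(bins$prob), sum(iv$r), tolerance = 1e-12)
})

test_that("bin probabilities are invariant to phantom-marker splitting", {
  iv <- data.frame(chr = 1L, left_snp = "a", right_snp = "c",
                   left_bp = 0.2e6, right_bp = 1.8e6, r = 0.03)
  one <- bin_crossover_probability(iv, c(`1` = 2e6))
  # split at 1.0 Mb with r partitioned additively in proportion to length
  frac <- (1.0e6 - 0.2e6) / (1.8e6 - 0.2e6)
  iv2 <- data.frame(chr = 1L, left_snp = c("a", "b"), right_snp = c("b", "c"),
                    left_bp = c(0.2e6, 1.0e6), right_bp = c(1.0e6, 1.8e6),
                    r = c(0.03 * frac, 0.03 * (1 - frac)))
  two <- bin_crossover_probability(iv2, c(`1` = 2e6))
  expect_equal(one$prob, two$prob, tolerance = 1e-12)
})

# simulate sex-specific bin tables from a known distance effect
simulate_bins <- function(n_bins, f_shape, noise_sd = 0.002, gc_beta = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- runif(2 * n_bins, 0.5, 60)
  sex <- rep(c("M", "F"), each = n_bins)
  gc <- runif(2 * n_bins, 35, 55)
  prob <- f_shape(d, sex) + gc_beta * (gc - 45) + rnorm(2 * n_bins, 0, noise_sd)
  mk <- function(s) data.frame(chr = 1L, bin = seq_len(n_bins),
                               start_bp = 0, mid_bp = 0,
                               prob = prob[sex == s], n_snps = 15,
                               dist_telomere_mb = d[sex == s],
                               gc_percent = gc[sex == s])
  list(male = mk("M"), female = mk("F"))
}

test_that("AIC selects the generating distance transform (cubic) almost always", {
  hits <- 0
  for (i in 1:60) {
    b <- simulate_bins(200, function(d, s)
      0.02 - 8e-4 * d + 1.6e-5 * d^2 - 9e-8 * d^3, seed = 5100 + i)
    fit <- fit_telomere_model(b$male, b$female)
    hits <- hits + (fit$chosen == "cubic")
  }
  expect_gte(hits / 60, 0.95)
})

test_that("sex-by-distance contrast recovers a male subtelomeric elevation", {
  b <- simulate_bins(400, function(d, s)
    0.012 + ifelse(s == "M", pmax(0, 18 - d) * 8e-4, 0), seed = 52)
  fit <- fit_telomere_model(b$male, b$female)
  nd <- data.frame(dist_telomere_mb = seq(1, 50, by = 0.5), n_snps = 15,
                   gc_percent = 45)
  pm <- predict(fit$best, cbind(nd, sex = "M"))
  pf <- predict(fit$best, cbind(nd, sex = "F"))
  diffs <- pm - pf
  expect_gt(diffs[1], 0)                      # elevated at the telomere
  cross <- nd$dist_telomere_mb[which(diffs <= 0)[1]]
  expect_gt(cross, 10); expect_lt(cross, 30)  # crossing near 18 Mb
})

test_that("a positive GC effect is detected", {
  b <- simulate_bins(1000, function(d, s) 0.015 - 1e-4 * d,
                     gc_beta = 3e-4, seed = 53)
  fit <- fit_telomere_model(b$male, b$female)
  co <- summary(fit$best)$coefficients
  expect_gt(co["gc_percent", "Estimate"], 0)
  expect_lt(co["gc_percent", "Pr(>|t|)"], 0.05)
})

test_that("broad-scale regressions recover construction: linearity, inverse rate, sex ratio", {
  set.seed(54)
  len <- seq(45e6, 280e6, length.out = 20)
  # obligate crossing over: 50 cM baseline + uniform 0.8 cM/Mb
  cmA <- 50 + 0.8 * len / 1e6 + rnorm(20, 0, 4)
  d <- data.frame(chr = 1:20, length_bp = len,
                  cm_averaged = cmA,
                  cm_female = cmA / 1.15,
                  cm_male = 1.31 * cmA / 1.15 + rnorm(20, 0, 2))
  br <- broadscale_regressions(d)
  s <- br$summary
  expect_gt(s$adj_r_squared[s$model == "cM~Mb"], 0.95)
  # cM/Mb decreases with length; the inverse fit beats the linear one
  expect_lt(s$aic[s$model == "cM/Mb~1/Mb"], s$aic[s$model == "cM/Mb~Mb"])
  expect_gt(s$slope[s$model == "cM/Mb~1/Mb"], 0)
  # male ~ female slope near the constructed 1.31
  fit_mf <- br$male_female_fit
  slope <- coef(fit_mf)[2]; se <- summary(fit_mf)$coefficients[2, 2]
  expect_lt(abs(slope - 1.31), 2 * se)
})

test_that("chromosome map lengths feed the broad-scale summary", {
  lm_map <- data.frame(snp = sprintf("s%d", 1:6),
                       chr = rep(1:2, each = 3), bp = rep(c(1e6, 2e6, 3e6), 2),
                       cM_averaged = c(0, 10, 20, 0, 15, 30),
                       cM_male = c(0, 12, 24, 0, 18, 36),
                       cM_female = c(0, 8, 16, 0, 12, 24))
  cl <- chromosome_map_lengths(lm_map, c(`1` = 100e6, `2` = 80e6))
  expect_equal(cl$cm_averaged, c(20, 30))
  expect_equal(cl$cm_male, c(24, 36))
  expect_equal(cl$length_bp, c(100e6, 80e6))
})
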
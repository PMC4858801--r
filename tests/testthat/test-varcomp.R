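# GRM construction, REML animal models, LRTs, bivariate models,
# reference-panel selection.

test_that("GRM diagonal carries 1 + F with the genomic inbreeding measure", {
  # individual heterozygous at every marker, p = 0.5 everywhere -> F = -1
  m <- 40
  map <- data.frame(snp = sprintf("s%d", 1:m), chr = 1L, bp = 1:m * 1e5)
  G <- matrix(1L, 4, m, dimnames = list(paste0("i", 1:4), map$snp))
  # add allele-frequency variation via two homozygous individuals
  G[3, ] <- 0L; G[4, ] <- 2L
  panel <- genotype_panel(map, G)
  A <- compute_grm(panel, freqs = rep(0.5, m))
  expect_equal(unname(diag(A)[1]), 0)      # 1 + F, F = -1
  expect_equal(unname(diag(A)[2]), 0)
  # duplicate individuals: off-diagonal equals their shared diagonal
  expect_equal(A["i1", "i2"], unname(diag(A)[1]))

  # population mean F is ~0 when genotypes are drawn at the given p
  set.seed(31)
  p <- runif(300, 0.1, 0.9)
  G2 <- sapply(p, function(pp) rbinom(200, 2, pp))
  rownames(G2) <- paste0("x", 1:200)
  map2 <- data.frame(snp = sprintf("t%d", 1:300), chr = 1L, bp = 1:300 * 1e4)
  A2 <- compute_grm(genotype_panel(map2, G2), freqs = p)
  Fh <- attr(A2, "F_hat")
  se <- sd(Fh) / sqrt(length(Fh))
  expect_lt(abs(mean(Fh)), 3 * se + 1e-3)
  expect_error(compute_grm(genotype_panel(map2, G2), freqs = rep(0, 300)),
               "monomorphic")
})

test_that("pedigree NRM reproduces textbook relationships", {
  ped <- data.frame(id = c("a", "b", "c", "d", "e"),
                    sire = c(NA, NA, "a", "a", "c"),
                    dam = c(NA, NA, "b", "b", "d"),
                    sex = c("M", "F", "M", "F", "M"))
  A <- pedigree_nrm(ped)
  expect_equal(A["a", "c"], 0.5)
  expect_equal(A["c", "d"], 0.5)      # full sibs
  expect_equal(A["e", "e"], 1.25)     # offspring of full sibs: F = 0.25
  expect_equal(A["a", "e"], 0.5)
})

test_that("REML matches the balanced half-sib ANOVA closed form", {
  set.seed(32)
  s <- 40; m <- 8
  sire <- rep(1:s, each = m)
  u <- rnorm(s, 0, 1)                         # sire sd 1 -> V_A = 4
  y <- 10 + u[sire] + rnorm(s * m, 0, 4)
  A <- halfsib_A(s, m)
  fit <- reml_fit(y, rownames(A), Klist = list(additive = A))
  MSB <- m * var(tapply(y, sire, mean))
  MSW <- sum((y - ave(y, sire))^2) / (s * (m - 1))
  sA_anova <- 4 * (MSB - MSW) / m
  sE_anova <- MSW - 3 * (MSB - MSW) / m
  expect_equal(unname(fit$sigma["additive"]), sA_anova, tolerance = 1e-6)
  expect_equal(unname(fit$sigma["residual"]), sE_anova, tolerance = 1e-6)
})

test_that("residual-only REML equals the OLS residual variance", {
  set.seed(33)
  n <- 150
  x <- rnorm(n); y <- 2 + 0.5 * x + rnorm(n, 0, 2)
  W <- cbind(1, x)
  fit <- reml_fit(y, paste0("u", 1:n), W = W, Klist = list())
  ols <- lm(y ~ x)
  expect_equal(unname(fit$sigma["residual"]),
               sum(residuals(ols)^2) / (n - 2), tolerance = 1e-7)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-7)
})

test_that("collapsed and dense REML agree on a repeated-measures design", {
  set.seed(34)
  A <- halfsib_A(12, 4)
  n_ind <- nrow(A)
  reps <- 3
  a <- draw_bv(A, 3)
  id <- rep(rownames(A), each = reps)
  y <- 5 + a[rep(seq_len(n_ind), each = reps)] + rnorm(n_ind * reps, 0, 2)
  fit_c <- reml_fit(y, id, Klist = list(additive = A))
  Z <- stats::model.matrix(~ 0 + factor(id, levels = rownames(A)))
  fit_d <- reml_dense(y, matrix(1, length(y), 1),
                      Vlist = list(additive = Z %*% A %*% t(Z)))
  expect_equal(unname(fit_c$sigma), unname(fit_d$sigma), tolerance = 1e-4)
})

test_that("animal model recovers simulated heritability and its identities hold", {
  set.seed(35)
  A <- halfsib_A(60, 5)
  n <- nrow(A); reps <- 4
  V_A <- 6; V_PE <- 3; V_E <- 21
  a <- draw_bv(A, V_A); pe <- rnorm(n, 0, sqrt(V_PE))
  id <- rep(rownames(A), each = reps)
  y <- 20 + (a + pe)[rep(1:n, each = reps)] + rnorm(n * reps, 0, sqrt(V_E))
  fit <- fit_animal_model(y, id, relationship = A, pe = TRUE)
  expect_true(fit$converged)
  h2_true <- V_A / (V_A + V_PE + V_E)
  expect_lt(abs(fit$h2 - h2_true), 2 * fit$h2_se)
  # identities: shares sum to one, V_P is the component sum
  comp <- setNames(fit$components$variance, fit$components$component)
  expect_equal(fit$h2 + fit$e2 + comp[["pe"]] / fit$V_P, 1)
  expect_equal(fit$V_P, sum(comp))
})

test_that("null simulation puts the additive variance at the boundary", {
  set.seed(36)
  A <- halfsib_A(30, 4)
  y <- rnorm(nrow(A), 10, 3)
  fit <- fit_animal_model(y, rownames(A), relationship = A, pe = FALSE)
  expect_lt(fit$h2, 0.1)
})

test_that("likelihood-ratio tests behave at the null and under signal", {
  expect_equal(lrt_random_effect(list(logLik = -10), list(logLik = -10))$p, 1)
  expect_error(lrt_random_effect(list(logLik = -11), list(logLik = -10)),
               "convergence")
  set.seed(37)
  A <- halfsib_A(80, 10)
  a <- draw_bv(A, 12)
  y <- a + rnorm(nrow(A), 0, sqrt(8))    # h2 = 0.6, n = 800
  full <- fit_animal_model(y, rownames(A), relationship = A, pe = FALSE)
  red <- fit_animal_model(y, rownames(A), relationship = NULL, pe = FALSE)
  lrt <- lrt_random_effect(full, red)
  expect_lt(lrt$p, 0.001)
  # boundary-mixture option halves the p-value
  expect_equal(lrt_random_effect(full, red, boundary = TRUE)$p, lrt$p / 2)
})

test_that("bivariate model recovers a shared architecture and r_A constraints nest", {
  set.seed(38)
  A <- halfsib_A(60, 6)
  n <- nrow(A); reps <- 3
  a <- draw_bv(A, 6)
  sex <- rep(c("M", "F"), length.out = n)
  id <- rep(rownames(A), each = reps)
  y <- a[rep(1:n, each = reps)] + rnorm(n * reps, 0, sqrt(14))
  bt <- bivariate_acc_tests(y, id, rep(sex, each = reps), A, pe = FALSE)
  expect_gt(bt$free$estimates$r_A, 0.5)
  # correlation indistinguishable from 1, distinguishable from 0
  expect_gt(bt$tests$p[bt$tests$test == "rA=0.999"], 0.05)
  expect_equal(bt$free$estimates$V_A_m, bt$free$estimates$V_A_f,
               tolerance = 0.8)
  # constrained fits cannot beat the free fit
  expect_lte(bt$rA0$logLik, bt$free$logLik + 1e-6)
  expect_lte(bt$equalVA$logLik, bt$free$logLik + 1e-6)
})

test_that("GRM- and NRM-based animal models agree on gene-dropped data", {
  # full-sib family structure so that the realised-relatedness signal is
  # large relative to GRM marker-sampling noise
  cfg <- sim_config(seed = 39, n_founders = 80, offspring_per_pair = c(5, 2),
                    interference_nu = 8)
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg)
  gen <- setNames(ped$generation, as.character(ped$id))
  tr <- gd$truth[gen[gd$truth$parent] == 1, ]
  fids <- sort(unique(tr$parent))
  fitG <- fit_animal_model(tr$acc_true, tr$parent,
                           fixed = data.frame(sex = tr$parent_sex),
                           relationship = compute_grm(gd$panel, ids = fids,
                                                      drop_monomorphic = TRUE),
                           pe = TRUE)
  fitN <- fit_animal_model(tr$acc_true, tr$parent,
                           fixed = data.frame(sex = tr$parent_sex),
                           relationship = pedigree_nrm(ped)[fids, fids],
                           pe = TRUE)
  joint_se <- sqrt(fitG$h2_se^2 + fitN$h2_se^2)
  expect_lt(abs(fitG$h2 - fitN$h2), 2 * joint_se)
})

test_that("reference-panel selection picks the hub of a star pedigree first", {
  k <- 12
  ids <- c("sire", paste0("o", 1:k))
  A <- matrix(0.25, k + 1, k + 1, dimnames = list(ids, ids))
  A["sire", ] <- 0.5; A[, "sire"] <- 0.5
  diag(A) <- 1
  sel1 <- select_reference_panel(A, 1)
  expect_equal(sel1[1], "sire")
  # exhaustive check of the first step's objective
  obj <- sapply(ids, function(i) unname(rowMeans(A)[i]) / A[i, i])
  expect_equal(names(which.max(obj)), "sire")
  # m = n selects everyone; objective nondecreasing in m
  seln <- select_reference_panel(A, k + 1)
  expect_setequal(seln, ids)
  expect_true(all(diff(attr(seln, "objective")) > -1e-9))
})
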
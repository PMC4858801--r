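# Single-locus phasing rules, crossover calling and the QC filters.

test_that("transmitted allele follows the single-locus transmission rules", {
  # offspring homozygous: that allele, provided the FID carries it
  expect_equal(transmitted_allele(1L, 0L, 2L), 0L)
  expect_equal(transmitted_allele(1L, 2L, 0L), 1L)
  expect_true(is.na(transmitted_allele(2L, 0L, 1L)))  # FID lacks allele A
  # heterozygous offspring resolved by a homozygous mate
  expect_equal(transmitted_allele(1L, 1L, 0L), 1L)
  expect_equal(transmitted_allele(1L, 1L, 2L), 0L)
  expect_true(is.na(transmitted_allele(1L, 1L, 1L)))
  expect_true(is.na(transmitted_allele(1L, 1L, NA)))
  expect_true(is.na(transmitted_allele(1L, NA, 0L)))
})

# brute-force oracle: enumerate every phased explanation of the subpedigree
# genotypes and collect the feasible origins of the transmitted allele
origin_oracle <- function(fid, tr, fa, mo) {
  alleles_of <- function(g) {
    if (is.na(g)) list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
    else list(switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L)))
  }
  feasible <- c(paternal = FALSE, maternal = FALSE)
  for (fg in alleles_of(fa)) for (mg in alleles_of(mo)) {
    for (pf in unique(fg)) for (pm in unique(mg)) {
      if (sum(c(pf, pm)) != fid) next     # must reproduce the FID genotype
      if (pf == tr && pm == (1L - tr)) feasible["paternal"] <- TRUE
      if (pm == tr && pf == (1L - tr)) feasible["maternal"] <- TRUE
    }
  }
  if (sum(feasible) == 1L) which(feasible) else NA_integer_
}

test_that("grandparental origin matches exhaustive enumeration over all configurations", {
  grid <- expand.grid(fid = 0:2, tr = 0:1,
                      fa = c(0:2, NA), mo = c(0:2, NA))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- as.integer(grandparental_origin(g$fid, g$tr, g$fa, g$mo))
    want <- origin_oracle(g$fid, g$tr, g$fa, g$mo)
    expect_identical(got, as.integer(want),
                     info = sprintf("fid=%s tr=%s fa=%s mo=%s", g$fid, g$tr, g$fa, g$mo))
  }
})

test_that("crossovers are counted as switches in grandparental origin", {
  expect_equal(call_crossovers(c(1L, 1L, 1L, 1L)), 0L)
  expect_equal(call_crossovers(c(1L, 1L, 2L, 2L)), 1L)
  expect_equal(call_crossovers(c(1L, 2L, 1L, 2L)), 3L)
  expect_equal(call_crossovers(integer(0)), 0L)
})

test_that("single-SNP origin runs are removed only when internal", {
  ph <- make_phase_set(list(
    g1 = list(`1` = c(1, 1, 2, 1, 1)),   # internal single -> removed
    g2 = list(`1` = c(1, 2, 2, 1)),      # run length 2 -> kept
    g3 = list(`1` = c(2, 1, 1, 1))))     # terminal single -> kept
  f <- filter_single_snp_runs(ph)
  expect_equal(f$n_removed, 1L)
  acc <- summarize_acc(f$phase)
  expect_equal(acc$acc[acc$gamete == "g1"], 0L)  # crossovers 2 -> 0
  expect_equal(acc$acc[acc$gamete == "g2"], 2L)
  expect_equal(acc$acc[acc$gamete == "g3"], 1L)
})

test_that("span filter removes only short-span double crossovers", {
  # 20 long-span doubles (~8 Mb) and one short (10 kb)
  origins <- list(); bp_list <- list()
  for (g in 1:20) {
    gid <- sprintf("L%02d", g)
    origins[[gid]] <- list(`1` = c(1, 1, 2, 2, 1, 1))
    bp_list[[gid]] <- list(`1` = c(1, 2, 3, 11, 12, 13) * 1e6 + g * 1000)
  }
  origins$S1 <- list(`1` = c(1, 1, 2, 2, 1, 1))
  bp_list$S1 <- list(`1` = c(1e6, 2e6, 2.004e6, 2.006e6, 2.01e6, 3e6))
  ph <- make_phase_set(origins, bp_list)
  f <- filter_short_double_crossovers(ph)
  expect_equal(f$stats$n_double_crossovers, 21L)
  expect_equal(f$stats$n_runs_removed, 1L)
  acc <- summarize_acc(f$phase)
  expect_equal(acc$acc[acc$gamete == "S1"], 0L)
  expect_true(all(acc$acc[grepl("^L", acc$gamete)] == 2L))
  expect_lt(f$stats$threshold_log10, f$stats$mean_log10_span)
})

test_that("span filter is skipped with a warning when doubles are scarce", {
  ph <- make_phase_set(list(g1 = list(`1` = c(1, 1, 2, 2))))
  expect_warning(f <- filter_short_double_crossovers(ph), "skipped")
  expect_equal(nrow(f$phase), nrow(ph))
})

test_that("filters never increase ACC; isolated single-SNP runs each remove exactly 2", {
  set.seed(42)
  for (rep in 1:20) {
    # arbitrary origin vectors: the filter chain can only reduce the count
    o <- sample(1:2, 30, replace = TRUE)
    ph <- make_phase_set(list(g = list(`1` = o)))
    before <- summarize_acc(ph)$acc
    f1 <- filter_single_snp_runs(ph)
    mid <- summarize_acc(f1$phase)$acc
    if (length(mid) == 0) mid <- 0L
    expect_lte(mid, before)
    f2 <- suppressWarnings(filter_short_double_crossovers(f1$phase))
    after <- summarize_acc(f2$phase)$acc
    if (length(after) == 0) after <- 0L
    expect_lte(after, mid)
  }
  for (rep in 1:10) {
    # isolated single-SNP runs (flanked by longer same-origin runs):
    # each removal cancels exactly the two crossovers around it
    base <- rep(sample(1:2, 1), 40)
    k <- sample(1:3, 1)
    at <- sort(sample(seq(5, 35, by = 5), k))
    o <- base; o[at] <- 3L - o[at]
    ph <- make_phase_set(list(g = list(`1` = o)))
    before <- summarize_acc(ph)$acc
    f1 <- filter_single_snp_runs(ph)
    mid <- summarize_acc(f1$phase)$acc
    expect_equal(f1$n_removed, k)
    expect_equal(before - mid, 2L * k)
  }
})

test_that("ACC summary aggregates over chromosomes", {
  ph <- make_phase_set(list(
    g1 = list(`1` = c(1, 1), `2` = c(2, 2)),
    g2 = list(`1` = c(1, 2), `2` = c(1, 1, 2))))
  acc <- summarize_acc(ph)
  expect_equal(acc$acc[acc$gamete == "g1"], 0L)
  expect_equal(acc$acc[acc$gamete == "g2"], 2L)
  expect_equal(acc$chr_1[acc$gamete == "g2"], 1L)
  expect_equal(acc$chr_2[acc$gamete == "g2"], 1L)
  expect_equal(acc$n_informative[acc$gamete == "g2"], 5L)
  # informative length: (last - first) per chromosome, summed
  expect_equal(acc$informative_length_bp[acc$gamete == "g1"], 2e6)
  expect_equal(acc$informative_length_bp[acc$gamete == "g2"], 1e6 + 2e6)
})
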
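# Core-haplotype tagging and haplotype-sharing distances.

make_haps <- function(rows, bp, pop = "pop") {
  H <- do.call(rbind, rows)
  haplotype_set(H, bp, pop)
}

test_that("only perfectly tagging core haplotypes are returned", {
  bp <- c(1:7) * 1e5
  # columns 1-6 form the core window, column 7 is the focal SNP
  h <- list(c(1, 0, 0, 1, 1, 0, 1),   # core A, focal 1
            c(1, 0, 0, 1, 1, 0, 1),
            c(0, 1, 1, 0, 0, 1, 0),   # core B, focal 0
            c(0, 1, 1, 0, 0, 1, 0),
            c(1, 1, 0, 0, 1, 1, 1),   # core C carried with both focal alleles
            c(1, 1, 0, 0, 1, 1, 0))
  hs <- make_haps(h, bp)
  cores <- find_core_haplotypes(hs, focal_idx = 7, core_length = 6)
  expect_equal(nrow(cores), 2L)
  expect_setequal(cores$tagged_allele, c(0, 1))
  expect_false("110011" %in% cores$core)   # impure haplotype excluded
})

test_that("a constructed population reproduces a 2-vs-5 tagging pattern", {
  set.seed(71)
  n_core <- 7
  bp <- seq_len(6 + 1 + 20) * 1e5          # 6 core + focal + 20 downstream
  cores <- unique(replicate(n_core, rbinom(6, 1, 0.5), simplify = FALSE))
  while (length(cores) < n_core) cores <- unique(c(cores, list(rbinom(6, 1, 0.5))))
  focal_allele <- c(0, 0, 1, 1, 1, 1, 1)   # two tag A(0), five tag G(1)
  rows <- list()
  for (k in seq_len(n_core)) {
    for (cp in 1:3) {
      rows[[length(rows) + 1L]] <- c(cores[[k]], focal_allele[k],
                                     rbinom(20, 1, 0.5))
    }
  }
  hs <- make_haps(rows, bp)
  found <- find_core_haplotypes(hs, focal_idx = 7, core_length = 6)
  expect_equal(nrow(found), 7L)
  expect_equal(sum(found$tagged_allele == 0), 2L)
  expect_equal(sum(found$tagged_allele == 1), 5L)
})

test_that("sharing distance is the bp distance to the first downstream mismatch", {
  bp <- c(1e6, 1.2e6, 1.5e6, 2e6, 2.5e6)   # SNPs 1-2 are a length-2 core
  core <- data.frame(core = "11", start_idx = 1L, end_idx = 2L,
                     tagged_allele = 1, stringsAsFactors = FALSE)
  focal <- make_haps(list(c(1, 1, 0, 1, 0)), bp, "focal")
  ref <- make_haps(list(c(1, 1, 0, 1, 1)), bp, "ref")   # mismatch at SNP 5
  out <- haplotype_sharing_length(core, focal, ref)
  expect_equal(out$n_pairs, 1L)
  expect_equal(out$distances$distance_bp, 2.5e6 - 1.2e6)
  expect_equal(out$n_censored, 0L)

  # mismatch at the first downstream SNP: minimal positive distance
  ref2 <- make_haps(list(c(1, 1, 1, 1, 0)), bp, "ref")
  out2 <- haplotype_sharing_length(core, focal, ref2)
  expect_equal(out2$distances$distance_bp, 1.5e6 - 1.2e6)

  # identical to region end: censored at the last compared SNP
  ref3 <- make_haps(list(c(1, 1, 0, 1, 0)), bp, "ref")
  out3 <- haplotype_sharing_length(core, focal, ref3)
  expect_equal(out3$n_censored, 1L)
  expect_equal(out3$distances$distance_bp, 2.5e6 - 1.2e6)

  # reference set lacking the core: n_pairs = 0, distinct from sharing 0
  ref4 <- make_haps(list(c(0, 1, 0, 1, 0)), bp, "ref")
  out4 <- haplotype_sharing_length(core, focal, ref4)
  expect_equal(out4$n_pairs, 0L)
  expect_true(is.na(out4$mean_bp))
})

test_that("pairwise sharing equals a brute-force all-pairs scan on a toy set", {
  set.seed(72)
  m <- 30
  bp <- sort(sample.int(4e6, m))
  core_idx <- 1:6
  core_seq <- rbinom(6, 1, 0.5)
  mk_pop <- function(n, carrier_prob = 0.6) {
    rows <- lapply(1:n, function(i) {
      h <- rbinom(m, 1, 0.5)
      if (runif(1) < carrier_prob) h[core_idx] <- core_seq
      h
    })
    make_haps(rows, bp)
  }
  focal <- mk_pop(5); ref <- mk_pop(5)
  core <- data.frame(core = paste(core_seq, collapse = ""),
                     start_idx = 1L, end_idx = 6L, tagged_allele = 1,
                     stringsAsFactors = FALSE)
  got <- haplotype_sharing_length(core, focal, ref)

  # independent oracle: naive double loop
  is_carrier <- function(set) apply(set$H[, core_idx, drop = FALSE], 1,
                                    function(x) all(x == core_seq))
  fc <- which(is_carrier(focal)); rc <- which(is_carrier(ref))
  dists <- c(); cens <- c()
  for (i in fc) for (j in rc) {
    walked <- 7:m
    mism <- walked[focal$H[i, walked] != ref$H[j, walked]]
    if (length(mism)) {
      dists <- c(dists, bp[mism[1]] - bp[6]); cens <- c(cens, FALSE)
    } else {
      dists <- c(dists, bp[m] - bp[6]); cens <- c(cens, TRUE)
    }
  }
  expect_equal(got$n_pairs, length(dists))
  expect_equal(got$distances$distance_bp, dists)
  expect_equal(got$distances$censored, cens)
  expect_equal(got$mean_bp, mean(dists[!cens]))
})

test_that("sharing is symmetric and nonincreasing under introduced mismatches", {
  bp <- seq_len(20) * 1e5
  core <- data.frame(core = "1111", start_idx = 1L, end_idx = 4L,
                     tagged_allele = 1, stringsAsFactors = FALSE)
  base <- c(rep(1, 4), rbinom(16, 1, 0.5))
  a <- make_haps(list(base), bp, "a")
  b <- make_haps(list(base), bp, "b")
  ab <- haplotype_sharing_length(core, a, b)
  ba <- haplotype_sharing_length(core, b, a)
  expect_equal(ab$distances, ba$distances)
  # flip a downstream allele: distance cannot increase
  b2 <- base; b2[10] <- 1 - b2[10]
  worse <- haplotype_sharing_length(core, a, make_haps(list(b2), bp, "b"))
  expect_lte(worse$mean_bp_all, ab$mean_bp_all)
})
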
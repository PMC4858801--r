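# Shared fixture builders. Everything is generated in code; no stored data.

# A phase set built by hand from per-gamete origin vectors.
# origins: named list gamete -> list(chr -> integer origin vector)
# bp defaults to 1 Mb spacing.
make_phase_set <- function(origins, bp_list = NULL, fid_sex = "F") {
  rows <- list()
  for (g in names(origins)) {
    for (cc in names(origins[[g]])) {
      o <- origins[[g]][[cc]]
      bp <- if (!is.null(bp_list)) bp_list[[g]][[cc]] else seq_along(o) * 1e6
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gamete = g, fid_sex = fid_sex, chr = as.integer(cc),
        snp = sprintf("s%s_%d", cc, seq_along(o)), bp = bp,
        origin = as.integer(o))
    }
  }
  ph <- data.table::rbindlist(rows)
  data.table::setorder(ph, gamete, chr, bp)
  class(ph) <- c("phase_set", class(ph))
  ph
}

# Phase sets simulated directly from per-interval recombination fractions:
# markers all informative, origin flips between adjacent markers with the
# interval's r. r_list: list(chr -> numeric vector of interval r).
simulate_phase_direct <- function(n_gametes, r_list, bp_list = NULL,
                                  sex = rep("F", n_gametes)) {
  origins <- list(); bps <- list()
  rows <- list()
  for (g in seq_len(n_gametes)) {
    gid <- sprintf("g%04d", g)
    for (cc in names(r_list)) {
      r <- r_list[[cc]]
      m <- length(r) + 1L
      o <- integer(m)
      o[1] <- sample(1:2, 1)
      flips <- runif(length(r)) < r
      for (k in seq_along(r)) o[k + 1L] <- if (flips[k]) 3L - o[k] else o[k]
      bp <- if (!is.null(bp_list)) bp_list[[cc]] else seq_len(m) * 1e6
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gamete = gid, fid_sex = sex[g], chr = as.integer(cc),
        snp = sprintf("s%s_%d", cc, seq_len(m)), bp = bp,
        origin = o)
    }
  }
  ph <- data.table::rbindlist(rows)
  data.table::setorder(ph, gamete, chr, bp)
  class(ph) <- c("phase_set", class(ph))
  ph
}

# Tiny gene-drop scenario for end-to-end checks.
small_sim <- function(seed = 1, snp_density = 4, n_founders = 16,
                      offspring_per_pair = c(3, 2), ...) {
  cfg <- sim_config(seed = seed, n_founders = n_founders,
                    offspring_per_pair = offspring_per_pair,
                    snp_density = snp_density, ...)
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg)
  list(cfg = cfg, ped = ped, gd = gd)
}

# Block-diagonal half-sib additive relationship over n individuals in
# families of `fam_size` (0.25 within family).
halfsib_A <- function(n_fam, fam_size) {
  n <- n_fam * fam_size
  A <- matrix(0, n, n)
  fam <- rep(seq_len(n_fam), each = fam_size)
  for (f in seq_len(n_fam)) {
    i <- which(fam == f)
    A[i, i] <- 0.25
  }
  diag(A) <- 1
  ids <- sprintf("hs%03d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  attr(A, "family") <- fam
  A
}

# Draw a multivariate-normal breeding value with covariance sigma2 * A.
draw_bv <- function(A, sigma2) {
  as.vector(t(chol(A)) %*% rnorm(nrow(A))) * sqrt(sigma2)
}
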
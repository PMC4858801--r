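# Gene dropping: founder haplotypes are simulated from allele frequencies
# and transmitted down the pedigree with explicitly simulated crossovers,
# recording the true crossover count and positions of every meiosis.

# Build the SNP map for a config: uniform placement per chromosome at the
# configured density, founder allele frequencies drawn from maf_range.
simulate_snp_map <- function(config) {
  maps <- lapply(seq_len(config$n_chromosomes), function(c) {
    L <- config$chromosome_lengths_bp[c]
    n <- max(2L, round(config$snp_density * L / 1e6))
    bp <- sort(sample.int(L, n))
    data.frame(chr = c, bp = bp)
  })
  map <- do.call(rbind, maps)
  map$snp <- sprintf("snp_c%d_%d", map$chr, ave(map$bp, map$chr, FUN = seq_along))
  freqs <- config$founder_allele_freqs
  if (is.null(freqs)) {
    map$freq <- runif(nrow(map), config$maf_range[1], config$maf_range[2])
  } else {
    map$freq <- rep_len(freqs, nrow(map))
  }
  if (any(map$freq <= 0 | map$freq >= 1))
    warnf("monomorphic SNPs (frequency 0 or 1) carry no information")
  map[, c("snp", "chr", "bp", "freq")]
}

# Founder haplotypes: sites independent Bernoulli(freq), or mosaics of a
# small pool of ancestral haplotypes per LD block (background LD).
simulate_founder_haplotypes <- function(config, map, n_haplotypes) {
  m <- nrow(map)
  if (config$founder_ld_blocks > 1L) {
    K <- config$founder_ld_blocks
    anc <- matrix(rbinom(K * m, 1L, rep(map$freq, each = K)), nrow = K)
    block <- ceiling(seq_len(m) / config$ld_block_snps)
    # block ids must not join across chromosomes
    block <- as.integer(factor(paste(map$chr, block)))
    H <- matrix(0L, n_haplotypes, m)
    for (b in unique(block)) {
      cols <- which(block == b)
      pick <- sample.int(K, n_haplotypes, replace = TRUE)
      H[, cols] <- anc[pick, cols, drop = FALSE]
    }
    H
  } else {
    matrix(rbinom(n_haplotypes * m, 1L, rep(map$freq, each = n_haplotypes)),
           nrow = n_haplotypes, byrow = FALSE)
  }
}

#' Gene-drop genotypes and gametes down a pedigree
#'
#' Simulates founder haplotypes, transmits them down the pedigree with
#' explicitly simulated crossovers (sex-specific maps, optional obligate
#' crossing over and interference), applies the configured genotyping error
#' and missingness, and records the true crossover count and positions of
#' every meiosis. The latent per-gamete crossover rate of a parent is
#' `mean(sex) + g + qtl + e` where `g` is a pedigree-correlated polygenic
#' value with variance `V_A_acc`, `qtl` an optional major-QTL deviation and
#' `e ~ N(0, V_R_acc)` a per-gamete residual.
#'
#' @param pedigree Pedigree `data.frame` (see [simulate_pedigree()]).
#' @param config A [sim_config()] object.
#' @param track_founders If `TRUE`, founder-haplotype labels are propagated
#'   alongside alleles and returned (used to audit inheritance).
#' @param map Optional fixed SNP map (`snp`, `chr`, `bp`, `freq`), e.g. to
#'   hold markers and population allele frequencies constant across
#'   replicate simulations; defaults to a fresh draw per call.
#' @return A list with:
#'   \describe{
#'     \item{panel}{A [genotype_panel()] of all pedigree members.}
#'     \item{truth}{`data.frame` of per-gamete truth: `gamete`, `parent`,
#'       `offspring`, `parent_sex`, `acc_true`.}
#'     \item{truth_counts}{Integer matrix gametes x chromosomes.}
#'     \item{truth_positions}{List (per gamete) of per-chromosome crossover
#'       bp positions.}
#'     \item{latent}{Per-individual polygenic values and per-gamete latent
#'       rates.}
#'     \item{founder_labels}{When tracked, a list of two label matrices.}
#'   }
#' @export
gene_drop <- function(pedigree, config, track_founders = FALSE, map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  ids <- as.character(ped$id)

  if (is.null(map)) map <- simulate_snp_map(config)
  m <- nrow(map)
  chr_cols <- split(seq_len(m), map$chr)

  qtl_col <- NULL
  if (!is.null(config$qtl_spec)) {
    qc <- config$qtl_spec
    cols <- chr_cols[[as.character(qc$chr)]]
    if (qc$snp_index > length(cols))
      stopf("qtl snp_index %d exceeds %d SNPs on chromosome %d",
            qc$snp_index, length(cols), qc$chr)
    qtl_col <- cols[qc$snp_index]
    if (!is.null(qc$freq)) map$freq[qtl_col] <- qc$freq
  }
  sex_maps <- config_maps(config)
  mu_map <- vapply(sex_maps, function(ms) sum(vapply(ms, `[[`, 0, "total_cm")) / 100, 0)
  n_chr <- config$n_chromosomes

  founders <- which(is.na(ped$sire) & is.na(ped$dam))
  non_founders <- which(!(is.na(ped$sire) & is.na(ped$dam)))
  if (length(non_founders) && any(is.na(ped$sire[non_founders]) != is.na(ped$dam[non_founders])))
    stopf("individuals with exactly one known parent are not supported by the simulator")

  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  rownames(H1) <- rownames(H2) <- ids
  FH <- simulate_founder_haplotypes(config, map, 2L * length(founders))
  H1[founders, ] <- FH[seq_along(founders) * 2L - 1L, , drop = FALSE]
  H2[founders, ] <- FH[seq_along(founders) * 2L, , drop = FALSE]
  if (track_founders) {
    L1 <- matrix(0L, n, m); L2 <- matrix(0L, n, m)
    rownames(L1) <- rownames(L2) <- ids
    L1[founders, ] <- rep(seq_along(founders) * 2L - 1L, m)
    L2[founders, ] <- rep(seq_along(founders) * 2L, m)
  }

  # polygenic values down the pedigree
  g <- setNames(numeric(n), ids)
  g[founders] <- rnorm(length(founders), 0, sqrt(config$V_A_acc))
  idx <- setNames(seq_len(n), ids)

  qtl_p <- if (!is.null(qtl_col)) map$freq[qtl_col] else NULL

  latent_rate <- function(i, sex) {
    mu <- if (sex == "M") config$acc_mean_male else config$acc_mean_female
    dev <- g[[i]]
    if (!is.null(qtl_col)) {
      qs <- config$qtl_spec$sex
      if (qs == "both" || qs == sex) {
        dose <- H1[i, qtl_col] + H2[i, qtl_col]
        dev <- dev + config$qtl_spec$effect * (dose - 2 * qtl_p)
      }
    }
    mu + dev
  }

  # one transmitted gamete; returns haplotype vector + crossover record
  transmit <- function(i, sex, t) {
    mei <- sim_meiosis(sex_maps[[sex]], t = t, obligate = config$obligate,
                       nu = config$interference_nu)
    hap <- integer(m)
    lab <- if (track_founders) integer(m) else NULL
    for (c in seq_len(n_chr)) {
      cols <- chr_cols[[c]]
      brk <- mei$positions_bp[[c]]
      seg <- if (length(brk)) findInterval(map$bp[cols], brk) else integer(length(cols))
      start <- sample(c(0L, 1L), 1L)
      use2 <- (start + seg) %% 2L == 1L
      hap[cols] <- ifelse(use2, H2[i, cols], H1[i, cols])
      if (track_founders) lab[cols] <- ifelse(use2, L2[i, cols], L1[i, cols])
    }
    list(hap = hap, lab = lab, counts = mei$counts, positions = mei$positions_bp)
  }

  records <- list(); counts <- list(); positions <- list(); latents <- list()
  for (r in non_founders) {
    for (side in c("sire", "dam")) {
      p <- as.character(ped[[side]][r])
      pi <- idx[[p]]
      sex <- if (side == "sire") "M" else "F"
      mu_m <- mu_map[[sex]]
      lat <- latent_rate(pi, sex) + rnorm(1, 0, sqrt(config$V_R_acc))
      # with the obligate Poisson count model only the non-obligate part of
      # the expectation scales with the individual; under the gamma-renewal
      # (interference) model the whole intensity scales
      t <- if (config$obligate && config$interference_nu == 1) {
        if (mu_m > n_chr) (lat - n_chr) / (mu_m - n_chr) else 1
      } else lat / mu_m
      tr <- transmit(pi, sex, max(0, t))
      if (side == "sire") H1[r, ] <- tr$hap else H2[r, ] <- tr$hap
      if (track_founders) {
        if (side == "sire") L1[r, ] <- tr$lab else L2[r, ] <- tr$lab
      }
      gid <- gamete_id(p, ped$id[r])
      records[[gid]] <- data.frame(gamete = gid, parent = p,
                                   offspring = as.character(ped$id[r]),
                                   parent_sex = sex,
                                   acc_true = sum(tr$counts),
                                   latent = lat,
                                   stringsAsFactors = FALSE)
      counts[[gid]] <- tr$counts
      positions[[gid]] <- tr$positions
    }
    # offspring polygenic value from parents (Mendelian sampling)
    g[r] <- (g[[idx[[as.character(ped$sire[r])]]]] +
             g[[idx[[as.character(ped$dam[r])]]]]) / 2 +
      rnorm(1, 0, sqrt(config$V_A_acc / 2))
  }

  G <- H1 + H2
  if (config$genotyping_error_rate > 0) {
    err <- which(runif(length(G)) < config$genotyping_error_rate)
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      G[err] <- (G[err] + shift) %% 3L
    }
  }
  if (config$genotyping_missing_rate > 0) {
    G[runif(length(G)) < config$genotyping_missing_rate] <- NA_integer_
  }
  colnames(G) <- map$snp

  truth <- do.call(rbind, records)
  rownames(truth) <- NULL
  cmat <- do.call(rbind, counts)
  out <- list(
    panel = genotype_panel(map, G),
    truth = truth,
    truth_counts = cmat,
    truth_positions = positions,
    latent = list(polygenic = g),
    pedigree = ped
  )
  if (track_founders) {
    out$founder_labels <- list(L1 = L1, L2 = L2)
    out$haplotypes <- list(H1 = H1, H2 = H2)
    out$founder_rows <- founders
  }
  out
}
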
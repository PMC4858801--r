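# Simulation configuration for the gene-dropping meiosis simulator.
#
# The genome template mirrors a 26-autosome ruminant karyotype (~2.45 Gb).
# Sex-specific genetic map lengths default to 2860 cM (female) and
# 1.31 x that (male), with each chromosome receiving an obligate 100 cM
# baseline plus a length-proportional share of the remainder, and with male
# crossover density elevated near chromosome ends.

# Physical autosome lengths (bp), largest to smallest; sum ~2.45 Gb.
.default_chrom_lengths <- function(n = 26L) {
  base <- c(275, 249, 224, 119, 108, 117, 100, 91, 95, 86, 62, 79, 83,
            63, 81, 72, 72, 68, 61, 51, 50, 51, 62, 42, 45, 44) * 1e6
  if (n == 26L) return(base)
  round(seq(from = base[1], to = base[26], length.out = n))
}

# Split a genome-wide map length over chromosomes: obligate baseline of
# 100 cM per chromosome, remainder proportional to physical length.
.default_chrom_cm <- function(lengths_bp, total_cm) {
  n <- length(lengths_bp)
  extra <- total_cm - 100 * n
  if (extra < 0) stopf("total map length %.1f cM < 100 cM per chromosome", total_cm)
  100 + extra * lengths_bp / sum(lengths_bp)
}

#' Configuration for the meiosis simulator
#'
#' Builds the parameter set consumed by [simulate_pedigree()], [gene_drop()]
#' and [validation_run()]. Defaults emulate a multi-generation pedigree with
#' repeated offspring per focal parent, 26 autosomes, sex-specific genetic
#' maps with male subtelomeric elevation, and a polygenic architecture for
#' autosomal crossover count (ACC) with heritability about 0.15.
#'
#' @param n_founders Number of founder individuals (generation 0).
#' @param n_generations Total number of generations including founders.
#' @param offspring_per_pair Expected offspring per mated pair; either a
#'   single value or one value per non-founder generation.
#' @param offspring_dist `"poisson"` or `"fixed"` litter sizes.
#' @param n_chromosomes Number of autosomes.
#' @param chromosome_lengths_bp Physical chromosome lengths in bp.
#' @param snp_density SNPs per Mb (uniformly placed per chromosome).
#' @param maf_range Range from which founder allele frequencies are drawn.
#' @param founder_allele_freqs Optional explicit per-SNP founder allele
#'   frequencies (recycled over markers); overrides `maf_range`.
#' @param map_female_cm,map_male_cm Per-chromosome genetic map lengths (cM).
#'   Defaults allocate `total_female_cm` (and 1.31 x for males) with an
#'   obligate 100 cM baseline per chromosome.
#' @param total_female_cm Genome-wide female map length used for defaults.
#' @param male_female_ratio Male:female genome-wide map-length ratio used
#'   for defaults.
#' @param male_subtel_factor Multiplicative elevation of male crossover
#'   density within `subtel_window_bp` of each chromosome end (1 = none).
#' @param subtel_window_bp Width of the subtelomeric window (bp).
#' @param interference_nu Gamma-renewal shape for crossover interference;
#'   1 gives no interference (Poisson placement).
#' @param obligate If `TRUE` (default) each chromosome receives at least one
#'   crossover: count = 1 + Poisson(expected - 1).
#' @param acc_mean_male,acc_mean_female Expected crossovers per gamete by sex
#'   of the parent. Defaults are implied by the maps (sum of cM / 100) and
#'   should normally be left as such.
#' @param h2_acc,V_P_acc Target heritability and phenotypic variance of ACC;
#'   used to derive latent variance components via
#'   [acc_variance_components()]. Ignored if `V_A_acc`/`V_R_acc` given.
#' @param V_A_acc,V_R_acc Latent additive-genetic and residual variances of
#'   the per-gamete crossover rate. If `NULL`, derived from `h2_acc`,
#'   `V_P_acc` and the count-sampling variance implied by the maps.
#' @param qtl_spec Optional list with elements `chr`, `snp_index` (within
#'   chromosome), `effect` (additive effect per copy of allele B on ACC),
#'   `sex` (`"F"`, `"M"` or `"both"`), and optionally `freq` (founder
#'   frequency forced at the QTL marker): a major QTL for ACC.
#' @param genotyping_missing_rate,genotyping_error_rate Per-call missing and
#'   error probabilities applied to simulated genotypes.
#' @param founder_ld_blocks If > 1, founder haplotypes are drawn as mosaics
#'   of this many ancestral haplotypes per LD block (creates background LD);
#'   0 or 1 draws sites independently.
#' @param ld_block_snps Number of SNPs per LD block when `founder_ld_blocks`
#'   is used.
#' @param seed Optional integer seed applied by the simulator entry points.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders = 52L,
                       n_generations = 3L,
                       offspring_per_pair = c(4, 2),
                       offspring_dist = c("fixed", "poisson"),
                       n_chromosomes = 26L,
                       chromosome_lengths_bp = NULL,
                       snp_density = 0.8,
                       maf_range = c(0.1, 0.5),
                       founder_allele_freqs = NULL,
                       map_female_cm = NULL,
                       map_male_cm = NULL,
                       total_female_cm = 2860,
                       male_female_ratio = 1.31,
                       male_subtel_factor = 3,
                       subtel_window_bp = 18e6,
                       interference_nu = 1,
                       obligate = TRUE,
                       acc_mean_male = NULL,
                       acc_mean_female = NULL,
                       h2_acc = 0.145,
                       V_P_acc = 29.56,
                       V_A_acc = NULL,
                       V_R_acc = NULL,
                       qtl_spec = NULL,
                       genotyping_missing_rate = 0,
                       genotyping_error_rate = 0,
                       founder_ld_blocks = 0L,
                       ld_block_snps = 25L,
                       seed = NULL) {
  offspring_dist <- match.arg(offspring_dist)
  if (is.null(chromosome_lengths_bp))
    chromosome_lengths_bp <- .default_chrom_lengths(n_chromosomes)
  n_chromosomes <- length(chromosome_lengths_bp)
  if (any(chromosome_lengths_bp <= 0)) stopf("chromosome lengths must be positive")

  if (is.null(map_female_cm))
    map_female_cm <- .default_chrom_cm(chromosome_lengths_bp, total_female_cm)
  if (is.null(map_male_cm))
    map_male_cm <- map_female_cm * male_female_ratio
  if (length(map_female_cm) != n_chromosomes || length(map_male_cm) != n_chromosomes)
    stopf("per-chromosome map lengths must match the number of chromosomes")
  if (any(map_female_cm <= 0) || any(map_male_cm <= 0))
    stopf("cM lengths must be > 0")

  mu_f <- sum(map_female_cm) / 100
  mu_m <- sum(map_male_cm) / 100
  acc_mean_female <- acc_mean_female %||% mu_f
  acc_mean_male <- acc_mean_male %||% mu_m

  for (r in c(genotyping_missing_rate, genotyping_error_rate))
    if (!is_number(r) || r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  if (!is_number(interference_nu) || interference_nu <= 0)
    stopf("interference_nu must be positive")
  if (n_founders < 2 || n_generations < 1)
    stopf("need at least 2 founders and 1 generation")

  if (is.null(V_A_acc) || is.null(V_R_acc)) {
    vc <- acc_variance_components(V_P = V_P_acc, h2 = h2_acc,
                                  mean_acc = (mu_f + mu_m) / 2,
                                  n_chromosomes = n_chromosomes,
                                  obligate = obligate,
                                  nu = interference_nu,
                                  map_cm = (map_female_cm + map_male_cm) / 2)
    V_A_acc <- V_A_acc %||% vc[["V_A"]]
    V_R_acc <- V_R_acc %||% vc[["V_R"]]
  }
  if (V_A_acc < 0 || V_R_acc < 0) stopf("variance components must be >= 0")

  if (!is.null(qtl_spec)) {
    need <- c("chr", "snp_index", "effect")
    if (!all(need %in% names(qtl_spec)))
      stopf("qtl_spec needs elements: %s", paste(need, collapse = ", "))
    qtl_spec$sex <- qtl_spec$sex %||% "both"
  }

  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_pair = offspring_per_pair,
    offspring_dist = offspring_dist,
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths_bp = as.numeric(chromosome_lengths_bp),
    snp_density = snp_density,
    maf_range = maf_range,
    founder_allele_freqs = founder_allele_freqs,
    map_female_cm = map_female_cm,
    map_male_cm = map_male_cm,
    male_subtel_factor = male_subtel_factor,
    subtel_window_bp = subtel_window_bp,
    interference_nu = interference_nu,
    obligate = obligate,
    acc_mean_male = acc_mean_male,
    acc_mean_female = acc_mean_female,
    V_A_acc = V_A_acc,
    V_R_acc = V_R_acc,
    qtl_spec = qtl_spec,
    genotyping_missing_rate = genotyping_missing_rate,
    genotyping_error_rate = genotyping_error_rate,
    founder_ld_blocks = as.integer(founder_ld_blocks),
    ld_block_snps = as.integer(ld_block_snps),
    seed = seed
  ), class = "sim_config")
}

#' Configuration preset for the detection-validation harness
#'
#' Conditions for [validation_run()]: a three-generation pedigree yielding
#' about 200 phase-informative gametes, SNP density raised to array scale
#' (24 SNPs/Mb, about 59k markers) so that the spacing of
#' single-locus-informative markers matches what a multipoint phaser
#' extracts from a 50K chip, and strong crossover interference
#' (gamma-renewal shape 8, in the range estimated for mammals), under which
#' genuinely close double crossovers are rare and the double-crossover QC
#' filters act almost exclusively on artefacts. Genotyping error and
#' missingness default to zero (the error-free validation design).
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
sim_config_validation <- function(...) {
  args <- list(...)
  defaults <- list(snp_density = 24, interference_nu = 8, obligate = FALSE)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Latent ACC variance components for a target phenotypic variance
#'
#' Under the obligate count model each chromosome contributes
#' `expected - 1` of Poisson sampling variance to the realised crossover
#' count, so the observed phenotypic variance of ACC is approximately
#' `V_A + V_R + (mean_acc - n_chromosomes)`. This helper inverts that
#' relationship: given a target phenotypic variance and heritability it
#' returns the latent additive (`V_A`) and residual (`V_R`) variances that
#' the simulator should use so that the realised phenotype matches the
#' target. Without obligate crossovers the count-sampling variance is the
#' full mean. Under the gamma-renewal interference model (`nu > 1`) the
#' asymptotic variance `mean / nu` understates the truth because each
#' chromosome map is only about one mean inter-crossover spacing long
#' (edge effects dominate), so when per-chromosome map lengths are
#' supplied the sampling variance is calibrated by a short Monte-Carlo run
#' of the renewal process (deterministic: an isolated, fixed-seed RNG
#' stream that does not disturb the caller's).
#'
#' @param V_P Target phenotypic variance of ACC.
#' @param h2 Target narrow-sense heritability.
#' @param mean_acc Expected crossovers per gamete (sex-averaged).
#' @param n_chromosomes Number of autosomes.
#' @param obligate Whether the obligate count model is used.
#' @param nu Gamma-renewal interference shape (1 = none).
#' @param map_cm Optional per-chromosome map lengths (cM) used to calibrate
#'   the renewal-model count variance.
#' @return Named vector with `V_A`, `V_R` and `V_count` (sampling variance).
#' @export
acc_variance_components <- function(V_P, h2, mean_acc, n_chromosomes = 26,
                                    obligate = TRUE, nu = 1, map_cm = NULL) {
  V_count <- if (nu != 1) {
    if (is.null(map_cm)) mean_acc / nu
    else .renewal_count_variance(map_cm, nu) * mean_acc / (sum(map_cm) / 100)
  } else if (obligate) max(0, mean_acc - n_chromosomes)
    else mean_acc
  V_A <- h2 * V_P
  V_R <- V_P - V_A - V_count
  if (V_R < 0) {
    warnf("count-sampling variance %.2f exceeds target residual variance; V_R set to 0",
          V_count)
    V_R <- 0
  }
  c(V_A = V_A, V_R = V_R, V_count = V_count)
}

# Monte-Carlo variance of the total crossover count under the stationary
# gamma-renewal model, at unit rate scaling. Fixed internal seed; the
# caller's RNG state is saved and restored.
.renewal_count_variance <- function(map_cm, nu, n_rep = 4000L) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(285714L)
  tot <- vapply(seq_len(n_rep), function(i)
    sum(vapply(map_cm, function(L)
      length(gamma_renewal_positions(L, nu)), 0L)), 0)
  var(tot)
}
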
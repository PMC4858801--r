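# Fine- and broad-scale recombination landscape.

#' Crossover probability in fixed-width genomic bins
#'
#' Sums adjacent-interval recombination fractions into bins (default 1 Mb)
#' along each chromosome. An interval whose flanking SNPs straddle a bin
#' boundary contributes `r * N_boundary / N_adjSNP` to the left bin, where
#' `N_boundary` is the number of bases from the left SNP to the boundary
#' and `N_adjSNP` the number of bases to the closest SNP in the adjacent
#' bin; the remainder goes to the adjacent bin. Intervals spanning more
#' than two bins are split proportionally per bin. Total probability per
#' chromosome is conserved exactly.
#'
#' @param intervals Interval table from [estimate_interval_rf()] (or the
#'   `intervals*` elements of [build_map()]).
#' @param chromosome_lengths_bp Named or ordered vector of chromosome
#'   lengths in bp.
#' @param bin_size Bin width in bp (default 1e6).
#' @param gc_table Optional `data.frame` (`chr`, `bin`, `gc_percent`)
#'   merged onto the result.
#' @return `data.frame` with one row per (chromosome, bin): `chr`, `bin`
#'   (1-based), `start_bp`, `mid_bp`, `prob`, `n_snps`,
#'   `dist_telomere_mb`, and `gc_percent` when supplied.
#' @export
bin_crossover_probability <- function(intervals, chromosome_lengths_bp,
                                      bin_size = 1e6, gc_table = NULL) {
  iv <- intervals[!is.na(intervals$r), , drop = FALSE]
  chrs <- sort(unique(intervals$chr))
  out <- list()
  n_multibin <- 0L
  for (cc in chrs) {
    L <- if (!is.null(names(chromosome_lengths_bp)))
      chromosome_lengths_bp[[as.character(cc)]] else chromosome_lengths_bp[[cc]]
    if (is.null(L) || is.na(L)) stopf("no chromosome length for chromosome %s", cc)
    n_bins <- max(1L, ceiling(L / bin_size))
    prob <- numeric(n_bins)
    n_snps <- numeric(n_bins)
    ivc <- iv[iv$chr == cc, , drop = FALSE]
    if (nrow(ivc)) {
      for (i in seq_len(nrow(ivc))) {
        a <- ivc$left_bp[i]; b <- ivc$right_bp[i]; r <- ivc$r[i]
        if (b <= a) { b1 <- min(n_bins, 1L + a %/% bin_size); prob[b1] <- prob[b1] + r; next }
        first <- min(n_bins, 1L + a %/% bin_size)
        last <- min(n_bins, 1L + (b - 1) %/% bin_size)
        if (last > first + 1L) n_multibin <- n_multibin + 1L
        for (bn in first:last) {
          lo <- max(a, (bn - 1) * bin_size)
          hi <- min(b, bn * bin_size)
          prob[bn] <- prob[bn] + r * (hi - lo) / (b - a)
        }
      }
      snp_bp <- unique(c(ivc$left_bp, ivc$right_bp))
      tab <- table(pmin(n_bins, 1L + snp_bp %/% bin_size))
      n_snps[as.integer(names(tab))] <- as.integer(tab)
    }
    mid <- ((seq_len(n_bins) - 0.5) * bin_size)
    out[[as.character(cc)]] <- data.frame(
      chr = cc, bin = seq_len(n_bins),
      start_bp = (seq_len(n_bins) - 1) * bin_size,
      mid_bp = mid, prob = prob, n_snps = n_snps,
      dist_telomere_mb = pmin(mid, L - mid) / 1e6)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (n_multibin > 0)
    warnf("%d intervals span more than 2 bins; split proportionally per bin",
          n_multibin)
  if (!is.null(gc_table)) {
    res <- merge(res, gc_table[, c("chr", "bin", "gc_percent")],
                 by = c("chr", "bin"), all.x = TRUE, sort = FALSE)
    res <- res[order(res$chr, res$bin), ]
    rownames(res) <- NULL
  }
  res
}

#' Model crossover probability against distance to the nearest telomere
#'
#' Fits Gaussian linear models of per-bin crossover probability on a set of
#' candidate transforms of distance to the nearest telomere (linear,
#' multiplicative inverse, quadratic, cubic, log10), each with sex as a
#' main effect and in interaction with the distance terms, plus the number
#' of SNPs per bin and (when present) GC content. The transform with the
#' lowest AIC wins. A companion model of the male/female probability ratio
#' (no sex term) is also fitted.
#'
#' @param bins_male,bins_female Bin tables from
#'   [bin_crossover_probability()] for the two sex-specific maps.
#' @param max_distance_mb Bins further than this from a telomere are
#'   excluded (default 60).
#' @param centromere_term Optional logical vector/column name flagging
#'   bins with a centromere in the window; added as a covariate if given.
#' @return List with `chosen` (name of best transform), `aic` (named
#'   vector), `fits` (all `lm` objects), `best` (the winning fit) and
#'   `ratio_fit`.
#' @export
fit_telomere_model <- function(bins_male, bins_female, max_distance_mb = 60,
                               centromere_term = NULL) {
  bm <- bins_male; bm$sex <- "M"
  bf <- bins_female; bf$sex <- "F"
  d <- rbind(bm, bf)
  d <- d[d$dist_telomere_mb <= max_distance_mb & d$dist_telomere_mb > 0, ]
  if (!is.null(centromere_term)) d$centromere <- rep_len(centromere_term, nrow(d))
  has_gc <- "gc_percent" %in% names(d) && any(!is.na(d$gc_percent))

  terms_of <- list(
    linear = "dist_telomere_mb",
    inverse = "I(1/dist_telomere_mb)",
    quadratic = "dist_telomere_mb + I(dist_telomere_mb^2)",
    cubic = "dist_telomere_mb + I(dist_telomere_mb^2) + I(dist_telomere_mb^3)",
    log = "log10(dist_telomere_mb)")

  build <- function(tt, with_sex = TRUE) {
    rhs <- if (with_sex) sprintf("sex * (%s) + n_snps", tt) else sprintf("(%s) + n_snps", tt)
    if (has_gc) rhs <- paste(rhs, "+ gc_percent")
    if (!is.null(centromere_term)) rhs <- paste(rhs, "+ centromere")
    as.formula(paste("prob ~", rhs))
  }
  fits <- lapply(terms_of, function(tt) lm(build(tt), data = d))
  ok <- !vapply(fits, is.null, TRUE)
  if (sum(ok) < 2) stopf("fewer than 2 candidate transforms estimable")
  aic <- vapply(fits, AIC, 0)
  chosen <- names(which.min(aic))

  ratio <- merge(bins_male[, c("chr", "bin", "prob")],
                 bins_female[, c("chr", "bin", "prob")],
                 by = c("chr", "bin"), suffixes = c("_m", "_f"))
  ratio <- merge(ratio, bf[, setdiff(names(bf), c("prob", "sex"))], by = c("chr", "bin"))
  ratio <- ratio[ratio$dist_telomere_mb <= max_distance_mb &
                 ratio$dist_telomere_mb > 0 & ratio$prob_f > 0, ]
  ratio$prob <- ratio$prob_m / ratio$prob_f
  ratio_fit <- lm(build(terms_of[[chosen]], with_sex = FALSE), data = ratio)

  list(chosen = chosen, aic = aic, fits = fits, best = fits[[chosen]],
       ratio_fit = ratio_fit, data = d)
}

#' Broad-scale regressions of map length on chromosome size
#'
#' Fits (i) a linear regression of linkage-map length (cM) on physical
#' length (bp), (ii) a multiplicative-inverse regression of chromosomal
#' recombination rate (cM/Mb) on physical length, compared with a linear
#' alternative by AIC, and (iii) a linear regression of male on female
#' chromosome map lengths.
#'
#' @param map_lengths `data.frame` with one row per chromosome: `chr`,
#'   `length_bp`, `cm_averaged`, `cm_male`, `cm_female`.
#' @return List of fitted models and a `summary` data.frame of
#'   coefficients, adjusted R-squared and p-values.
#' @export
broadscale_regressions <- function(map_lengths) {
  if (nrow(map_lengths) < 3) stopf("need at least 3 chromosomes")
  d <- map_lengths
  d$mb <- d$length_bp / 1e6
  d$rate <- d$cm_averaged / d$mb

  f_len <- lm(cm_averaged ~ mb, data = d)
  f_rate_inv <- lm(rate ~ I(1 / mb), data = d)
  f_rate_lin <- lm(rate ~ mb, data = d)
  f_sex <- lm(cm_male ~ cm_female, data = d)

  row <- function(name, fit) {
    s <- summary(fit)
    data.frame(model = name,
               slope = coef(fit)[2],
               adj_r_squared = s$adj.r.squared,
               p = s$coefficients[2, 4],
               aic = AIC(fit), row.names = NULL)
  }
  list(length_fit = f_len, rate_inverse_fit = f_rate_inv,
       rate_linear_fit = f_rate_lin, male_female_fit = f_sex,
       summary = rbind(row("cM~Mb", f_len),
                       row("cM/Mb~1/Mb", f_rate_inv),
                       row("cM/Mb~Mb", f_rate_lin),
                       row("male~female", f_sex)))
}

#' Per-chromosome map lengths from a linkage map
#'
#' @param linkage_map The `map` element of [build_map()].
#' @param chromosome_lengths_bp Physical chromosome lengths.
#' @return `data.frame` suitable for [broadscale_regressions()].
#' @export
chromosome_map_lengths <- function(linkage_map, chromosome_lengths_bp) {
  agg <- aggregate(cbind(cM_averaged, cM_male, cM_female) ~ chr,
                   data = linkage_map, FUN = max)
  data.frame(chr = agg$chr,
             length_bp = chromosome_lengths_bp[agg$chr],
             cm_averaged = agg$cM_averaged,
             cm_male = agg$cM_male,
             cm_female = agg$cM_female)
}
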
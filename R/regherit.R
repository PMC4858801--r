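# Regional heritability: partition additive genetic variance into sliding
# genomic windows, each fitted as its own genomic relationship matrix
# alongside the rest-of-genome GRM.

#' Sliding SNP windows over a panel
#'
#' Windows of `size` SNPs overlap by half their length and tile each
#' chromosome; the last window of a chromosome is truncated at the
#' chromosome end. Chromosomes with fewer than `size` SNPs yield a single
#' whole-chromosome window, flagged.
#'
#' @param panel A [genotype_panel()].
#' @param size Window size in SNPs (even; conventional values 150, 50, 20).
#' @param overlap Overlap in SNPs (default `size / 2`).
#' @return `data.frame` with `window`, `chr`, `start_idx`, `end_idx`
#'   (column indices into the panel), `median_bp`, `n_snps`, `whole_chr`.
#' @export
make_windows <- function(panel, size, overlap = size / 2) {
  if (size %% 2 != 0) stopf("window size must be even")
  step <- size - overlap
  out <- list()
  wid <- 0L
  for (cc in unique(panel$map$chr)) {
    cols <- which(panel$map$chr == cc)
    n <- length(cols)
    if (n < size) {
      wid <- wid + 1L
      out[[wid]] <- data.frame(window = wid, chr = cc, start_idx = cols[1],
                               end_idx = cols[n],
                               median_bp = median(panel$map$bp[cols]),
                               n_snps = n, whole_chr = TRUE)
      next
    }
    starts <- seq(1L, n - size + 1L, by = step)
    if (tail(starts, 1) + size - 1L < n) starts <- c(starts, n - size + 1L)
    for (s in starts) {
      wid <- wid + 1L
      idx <- cols[s:(s + size - 1L)]
      out[[wid]] <- data.frame(window = wid, chr = cc, start_idx = idx[1],
                               end_idx = idx[length(idx)],
                               median_bp = median(panel$map$bp[idx - cols[1] + cols[1]]),
                               n_snps = length(idx), whole_chr = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fit the regional heritability model for one window
#'
#' Three-component REML: a GRM restricted to the window's SNPs (regional
#' term `v`), a GRM of all other autosomal SNPs (`nv`), an optional
#' permanent-environment effect and residual. The regional term is tested
#' by LRT against the model without it; when the regional estimate sits on
#' the zero boundary the test is masked (`p = NA`), since a boundary
#' estimate cannot support a significant comparison.
#'
#' @param window One row of [make_windows()].
#' @param acc Crossover table (`fid`, `acc`, optional `sex`, `fhat`).
#' @param panel A [genotype_panel()] of focal individuals.
#' @param grm_all Optional precomputed whole-genome GRM (with
#'   `n_markers` attribute) to derive the complement GRM cheaply.
#' @param pe Include permanent-environment effect.
#' @return One-row `data.frame` with variance components, `h2_regional`
#'   (share of phenotypic variance), LRT `chi2`/`p` and `boundary`.
#' @export
fit_regional_model <- function(window, acc, panel, grm_all = NULL, pe = TRUE) {
  fids <- sort(unique(as.character(acc$fid)))
  cols <- window$start_idx:window$end_idx
  sub_win <- genotype_panel(panel$map[cols, , drop = FALSE],
                            panel$geno[, cols, drop = FALSE])
  K_win <- compute_grm(sub_win, ids = fids, drop_monomorphic = TRUE)
  if (is.null(grm_all)) grm_all <- compute_grm(panel, ids = fids,
                                               drop_monomorphic = TRUE)
  m_all <- attr(grm_all, "n_markers")
  m_win <- attr(K_win, "n_markers")
  if (m_all - m_win < 2) stopf("regional window leaves no complement markers")
  # marker-average identity: A_all * m_all = A_win * m_win + A_rest * m_rest
  K_rest <- (grm_all[fids, fids] * m_all - K_win * m_win) / (m_all - m_win)

  fixed <- NULL
  if ("sex" %in% names(acc) && length(unique(acc$sex)) > 1) fixed <- data.frame(sex = acc$sex)
  if ("fhat" %in% names(acc))
    fixed <- if (is.null(fixed)) data.frame(fhat = acc$fhat) else cbind(fixed, fhat = acc$fhat)
  pe_use <- pe && max(table(acc$fid)) >= 2

  full <- fit_animal_model(acc$acc, acc$fid, fixed = fixed, relationship = K_rest,
                           pe = pe_use, extra_random = list(regional = K_win))
  red <- fit_animal_model(acc$acc, acc$fid, fixed = fixed, relationship = K_rest,
                          pe = pe_use)
  lrt <- lrt_random_effect(full, red)

  comp <- full$components
  v_reg <- comp$variance[comp$component == "regional"]
  v_reg_se <- comp$se[comp$component == "regional"]
  boundary <- comp$boundary[comp$component == "regional"]
  data.frame(window = window$window, chr = window$chr,
             median_bp = window$median_bp, n_snps = window$n_snps,
             v_regional = v_reg, v_regional_se = v_reg_se,
             v_rest = comp$variance[comp$component == "additive"],
             V_P = full$V_P,
             h2_regional = v_reg / full$V_P,
             h2_regional_se = v_reg_se / full$V_P,
             chi2 = lrt$chi2,
             p = ifelse(boundary, NA_real_, lrt$p),
             boundary = boundary,
             logLik_full = full$logLik, logLik_reduced = red$logLik)
}

#' Regional heritability scan
#'
#' Fits [fit_regional_model()] for every sliding window and applies the
#' overlap-aware Bonferroni threshold `alpha / (n_windows / 2)` (each
#' genomic region is modelled twice because windows overlap by half).
#'
#' @param panel A [genotype_panel()] of focal individuals.
#' @param acc Crossover table.
#' @param size Window size in SNPs.
#' @param alpha Experiment-wide error rate.
#' @param pe Include permanent-environment effect.
#' @param windows Optional precomputed window table (default
#'   `make_windows(panel, size)`).
#' @return List with `scan` (one row per window), `threshold` and
#'   `n_windows`.
#' @export
regional_scan <- function(panel, acc, size = 20L, alpha = 0.05, pe = TRUE,
                          windows = NULL) {
  if (is.null(windows)) windows <- make_windows(panel, size)
  fids <- sort(unique(as.character(acc$fid)))
  grm_all <- compute_grm(panel, ids = fids, drop_monomorphic = TRUE)
  rows <- lapply(seq_len(nrow(windows)), function(i)
    fit_regional_model(windows[i, ], acc, panel, grm_all = grm_all, pe = pe))
  scan <- do.call(rbind, rows)
  thr <- alpha / (nrow(windows) / 2)
  scan$significant <- !is.na(scan$p) & scan$p < thr
  list(scan = scan, threshold = thr, n_windows = nrow(windows))
}
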
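# Mixed-model genome-wide association of autosomal crossover count.
#
# Each SNP is fitted as a fixed genotype factor (2 or 3 observed classes)
# inside the animal model. By default the variance components are
# estimated once under the null model and held fixed across SNPs
# (the standard population-parameters-previously-determined shortcut),
# which makes the per-SNP test a GLS Wald test on the collapsed
# individual-mean scale; `refit = TRUE` re-estimates components per SNP.

#' Genomic-control parameter from Wald statistics
#'
#' `lambda = median(chi2) / median(null chi2)`. Statistics with 1 df are
#' mapped onto the 2-df scale through their p-value quantiles so that runs
#' with a mixture of 2- and 3-level SNP factors pool correctly.
#'
#' @param chi2 Wald statistics.
#' @param df Degrees of freedom per statistic (1 or 2).
#' @return The genomic-control parameter.
#' @export
genomic_lambda <- function(chi2, df) {
  ok <- is.finite(chi2) & chi2 >= 0
  chi2 <- chi2[ok]; df <- rep_len(df, length(ok))[ok]
  if (!length(chi2)) return(NA_real_)
  conv <- ifelse(df == 2, chi2,
                 qchisq(pchisq(chi2, df, lower.tail = FALSE), 2, lower.tail = FALSE))
  median(conv) / qchisq(0.5, 2)
}

#' Effective number of tests from local linkage disequilibrium
#'
#' Sliding-window effective-test count: the first SNP contributes 1 and
#' every later SNP contributes `sqrt(1 - max r2)` with the preceding (up
#' to) `window - 1` SNPs on the same chromosome, where `r2` is the squared
#' genotype correlation. The genome-wide significance threshold is
#' `alpha / n_eff`.
#'
#' @param panel A [genotype_panel()].
#' @param ids Optional subset of individuals for LD estimation.
#' @param window Sliding-window size in SNPs (default 50).
#' @param alpha Experiment-wide error rate (default 0.05).
#' @return List with `n_eff`, `threshold` and the per-SNP contributions.
#' @export
effective_tests <- function(panel, ids = NULL, window = 50L, alpha = 0.05) {
  G <- panel$geno
  if (!is.null(ids)) G <- G[as.character(ids), , drop = FALSE]
  contrib <- numeric(ncol(G))
  for (cc in unique(panel$map$chr)) {
    cols <- which(panel$map$chr == cc)
    X <- G[, cols, drop = FALSE]
    for (j in seq_along(cols)) {
      if (j == 1L) { contrib[cols[j]] <- 1; next }
      prev <- max(1L, j - (window - 1L)):(j - 1L)
      x <- X[, j]
      if (all(is.na(x)) || var(x, na.rm = TRUE) == 0) {
        warnf("SNP %s carries no LD information; contribution set to 1",
              panel$map$snp[cols[j]])
        contrib[cols[j]] <- 1
        next
      }
      r2 <- suppressWarnings(
        cor(x, X[, prev, drop = FALSE], use = "pairwise.complete.obs"))^2
      r2max <- suppressWarnings(max(r2, na.rm = TRUE))
      if (!is.finite(r2max)) r2max <- 0
      contrib[cols[j]] <- sqrt(max(0, 1 - r2max))
    }
  }
  n_eff <- sum(contrib)
  list(n_eff = n_eff, threshold = significance_threshold(n_eff, alpha),
       contributions = contrib)
}

#' Multiple-testing significance threshold
#'
#' @param n_eff Effective number of tests.
#' @param alpha Experiment-wide error rate.
#' @return `alpha / n_eff`.
#' @export
significance_threshold <- function(n_eff, alpha = 0.05) alpha / n_eff

#' Variance explained by one SNP
#'
#' `V_SNP = 2pq * alpha^2` with the average allele-substitution effect
#' `alpha = a + d(p - q)`, where `a` is half the difference between the
#' homozygote effects (signed towards BB), `d` the deviation of the
#' heterozygote effect from their midpoint, and `p`, `q` the frequencies of
#' alleles A and B. Effects are relative to a model intercept at genotype
#' AA (so the AA effect is 0). This is the additive variance of the locus
#' under Hardy-Weinberg class frequencies, i.e. the variance of the fitted
#' values from the frequency-weighted regression of genotype-class means on
#' allele dosage. `prop_VA` is `V_SNP / (V_SNP + V_A)` with `V_A` the
#' additive variance from a model excluding the SNP.
#'
#' @param p,q Frequencies of alleles A and B (`p + q = 1`).
#' @param effect_AB,effect_BB Genotype effects relative to AA.
#' @param V_A_without_snp Additive genetic variance from a model without
#'   the SNP fixed effect (optional).
#' @return List with `a`, `d`, `V_SNP` and `prop_VA`.
#' @export
snp_variance <- function(p, q, effect_AB, effect_BB, V_A_without_snp = NA_real_) {
  if (abs(p + q - 1) > 1e-8) stopf("p + q must equal 1")
  if (p <= 0 || p >= 1) stopf("allele frequency must lie in (0, 1)")
  a <- effect_BB / 2
  d <- effect_AB - a
  V_SNP <- 2 * p * q * (a + d * (p - q))^2
  list(a = a, d = d, V_SNP = V_SNP,
       prop_VA = if (is.na(V_A_without_snp)) NA_real_ else
         V_SNP / (V_SNP + V_A_without_snp))
}

#' Mixed-model GWAS of crossover counts
#'
#' Fits the animal model per SNP with genotype as a fixed factor and
#' reports Wald tests, genomic control, the LD-based multiple-testing
#' threshold and per-SNP variance explained. In trans mode the response to
#' a SNP on chromosome `c` is the ACC minus the crossovers on chromosome
#' `c`, isolating genome-wide (trans-acting) rate variation.
#'
#' @param acc Crossover table from [summarize_acc()] (or compatible), with
#'   columns `gamete`, `fid`, `acc` and `chr_<k>` per-chromosome counts
#'   (required for `trans = TRUE`). A `sex` column is used for stratum
#'   subsetting, and optional `fhat` is fitted as a covariate.
#' @param panel A [genotype_panel()] with genotypes of the focal
#'   individuals.
#' @param relationship Additive relationship matrix (pedigree NRM by
#'   common practice; a GRM also works).
#' @param stratum `"all"`, `"female"` or `"male"`.
#' @param trans Use the trans-ACC response (ACC minus the focal SNP's
#'   chromosome).
#' @param method `"p3d"` (variance components fixed at their null-model
#'   estimates) or `"refit"` (re-estimated per SNP).
#' @param window,alpha Passed to [effective_tests()].
#' @param pe Include the permanent-environment random effect.
#' @return Object of class `gwas_run`: per-SNP records, `lambda`,
#'   `n_eff`, `threshold` and the null-model fit(s).
#' @export
run_gwas <- function(acc, panel, relationship,
                     stratum = c("all", "female", "male"),
                     trans = FALSE, method = c("p3d", "refit"),
                     window = 50L, alpha = 0.05, pe = TRUE) {
  stratum <- match.arg(stratum)
  method <- match.arg(method)
  d <- acc
  if (stratum == "female") d <- d[d$sex == "F", , drop = FALSE]
  if (stratum == "male") d <- d[d$sex == "M", , drop = FALSE]
  if (!nrow(d)) stopf("no observations in stratum '%s'", stratum)
  d$fid <- as.character(d$fid)
  fids <- sort(unique(d$fid))
  absent <- setdiff(fids, rownames(panel$geno))
  if (length(absent))
    stopf("panel lacks genotypes for %d focal individuals", length(absent))

  fixed <- NULL
  if (stratum == "all" && length(unique(d$sex)) > 1) fixed <- data.frame(sex = d$sex)
  if ("fhat" %in% names(d)) {
    fixed <- if (is.null(fixed)) data.frame(fhat = d$fhat) else cbind(fixed, fhat = d$fhat)
  }
  pe_use <- pe && max(table(d$fid)) >= 2

  chr_cols <- grep("^chr_", names(d), value = TRUE)
  responses <- if (trans) {
    if (!length(chr_cols)) stopf("trans mode needs per-chromosome count columns")
    chrs_needed <- unique(panel$map$chr)
    setNames(lapply(chrs_needed, function(cc) {
      col <- paste0("chr_", cc)
      if (!col %in% names(d)) stopf("missing per-chromosome column %s", col)
      d$acc - d[[col]]
    }), as.character(chrs_needed))
  } else {
    list(all = d$acc)
  }

  # null model (and P3D machinery) per distinct response
  nulls <- lapply(responses, function(yy)
    fit_animal_model(yy, d$fid, fixed = fixed, relationship = relationship,
                     pe = pe_use))
  G <- panel$geno[fids, , drop = FALSE]

  recs <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    cc <- panel$map$chr[j]
    null <- if (trans) nulls[[as.character(cc)]] else nulls[[1]]
    yy <- if (trans) responses[[as.character(cc)]] else responses[[1]]
    g <- G[, j]
    classes <- sort(unique(g[!is.na(g)]))
    if (length(classes) < 2) next
    gfac <- factor(g[match(d$fid, fids)], levels = classes)
    if (method == "p3d") {
      res <- .wald_p3d(null$fit, gfac)
    } else {
      fx <- if (is.null(fixed)) data.frame(geno = gfac) else cbind(fixed, geno = gfac)
      full <- tryCatch(
        fit_animal_model(yy, d$fid, fixed = fx, relationship = relationship,
                         pe = pe_use),
        error = function(e) NULL)
      res <- if (is.null(full)) NULL else .wald_refit(full, levels(gfac))
    }
    if (is.null(res)) next
    p_b <- mean(g, na.rm = TRUE) / 2
    vs <- if (p_b > 0 && p_b < 1 && !is.na(res$effect_BB)) {
      snp_variance(1 - p_b, p_b, ifelse(is.na(res$effect_AB), 0, res$effect_AB),
                   res$effect_BB,
                   V_A_without_snp = null$components$variance[
                     match("additive", null$components$component)])
    } else list(V_SNP = NA_real_, prop_VA = NA_real_)
    recs[[j]] <- data.frame(
      snp = panel$map$snp[j], chr = cc, bp = panel$map$bp[j],
      stratum = stratum, n_classes = length(classes),
      effect_AB = res$effect_AB, se_AB = res$se_AB,
      effect_BB = res$effect_BB, se_BB = res$se_BB,
      chi2 = res$chi2, df = res$df,
      p = pchisq(res$chi2, res$df, lower.tail = FALSE),
      V_SNP = vs$V_SNP, prop_VA = vs$prop_VA,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records) || !nrow(records)) stopf("no testable SNPs in stratum '%s'", stratum)

  lambda <- genomic_lambda(records$chi2, records$df)
  records$p_corrected <- records$p
  if (is.finite(lambda) && lambda > 1) {
    records$p_corrected <- pchisq(records$chi2 / lambda, records$df,
                                  lower.tail = FALSE)
  }
  et <- effective_tests(panel, ids = fids, window = window, alpha = alpha)
  structure(list(records = records, lambda = lambda, n_eff = et$n_eff,
                 threshold = et$threshold, stratum = stratum, trans = trans,
                 nulls = if (trans) nulls else nulls[1]),
            class = "gwas_run")
}

# GLS Wald test of a genotype factor with variance components fixed at the
# null fit (collapsed scale).
.wald_p3d <- function(fit, gfac) {
  cd <- fit$collapsed
  g_ind <- gfac[match(cd$levels, as.character(cd$f))]
  # genotype must be constant within individual: gfac is indexed per obs
  g_ind <- tapply(as.character(gfac), cd$f, function(v) v[1])[cd$levels]
  keep <- !is.na(g_ind)
  if (sum(keep) < 3) return(NULL)
  lv <- levels(gfac)
  Xg <- stats::model.matrix(~ factor(g_ind[keep], levels = lv))[, -1, drop = FALSE]
  if (any(colSums(Xg) == 0)) Xg <- Xg[, colSums(Xg) > 0, drop = FALSE]
  if (!ncol(Xg)) return(NULL)
  W <- cbind(cd$W[keep, , drop = FALSE], Xg)
  if (all(keep)) {
    R <- fit$chol_Sigma
    Wt <- backsolve(R, W, transpose = TRUE)
    Mt <- backsolve(R, cd$M, transpose = TRUE)
  } else {
    sig <- fit$sigma
    k <- length(fit$Klist)
    Sigma <- diag(sig[["residual"]] / cd$ni[keep], sum(keep))
    for (jj in seq_len(k))
      Sigma <- Sigma + sig[[jj]] * fit$Klist[[jj]][keep, keep]
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Wt <- backsolve(R, W, transpose = TRUE)
    Mt <- backsolve(R, cd$M[keep], transpose = TRUE)
  }
  XtX <- crossprod(Wt)
  vb <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(vb)) return(NULL)
  b <- drop(vb %*% crossprod(Wt, Mt))
  gi <- (ncol(W) - ncol(Xg) + 1):ncol(W)
  bg <- b[gi]
  Vg <- vb[gi, gi, drop = FALSE]
  chi2 <- tryCatch(drop(t(bg) %*% solve(Vg, bg)), error = function(e) NA_real_)
  if (!is.finite(chi2)) return(NULL)
  eff <- setNames(rep(NA_real_, 2), c("1", "2"))
  ses <- eff
  cn <- colnames(Xg)
  for (ii in seq_along(gi)) {
    lvl <- sub(".*\\)", "", cn[ii])
    eff[lvl] <- bg[ii]
    ses[lvl] <- sqrt(Vg[ii, ii])
  }
  list(chi2 = chi2, df = length(gi),
       effect_AB = eff[["1"]], se_AB = ses[["1"]],
       effect_BB = eff[["2"]], se_BB = ses[["2"]])
}

# Wald test from a refitted model: joint test on the genotype-factor terms.
.wald_refit <- function(full, lv) {
  nm <- names(full$beta)
  gi <- grep("^geno", nm)
  if (!length(gi)) return(NULL)
  bg <- full$beta[gi]
  Vg <- full$vcov_beta[gi, gi, drop = FALSE]
  chi2 <- tryCatch(drop(t(bg) %*% solve(Vg, bg)), error = function(e) NA_real_)
  if (!is.finite(chi2)) return(NULL)
  eff <- setNames(rep(NA_real_, 2), c("1", "2"))
  ses <- eff
  for (ii in seq_along(gi)) {
    lvl <- sub("^geno", "", nm[gi[ii]])
    if (lvl %in% names(eff)) { eff[lvl] <- bg[ii]; ses[lvl] <- sqrt(Vg[ii, ii]) }
  }
  list(chi2 = chi2, df = length(gi),
       effect_AB = eff[["1"]], se_AB = ses[["1"]],
       effect_BB = eff[["2"]], se_BB = ses[["2"]])
}

#' @export
print.gwas_run <- function(x, ...) {
  cat(sprintf("GWAS (%s%s): %d SNPs, lambda = %.3f, n_eff = %.2f, threshold = %.3g\n",
              x$stratum, if (x$trans) ", trans" else "", nrow(x$records),
              x$lambda, x$n_eff, x$threshold))
  top <- x$records[order(x$records$p), ][1, ]
  cat(sprintf("top hit: %s (chr %s, p = %.3g)\n", top$snp, top$chr, top$p))
  invisible(x)
}
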
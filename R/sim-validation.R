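#' Detection-accuracy validation by repeated simulation
#'
#' Runs the full crossover-detection pipeline (subpedigree construction,
#' Mendelian QC, phasing, crossover calling and both double-crossover
#' filters) on repeated gene-drop simulations over a single pedigree, and
#' regresses detected on true autosomal crossover count (i) within each
#' simulation across gametes and (ii) within each gamete across
#' simulations. Gametes whose across-simulation adjusted R-squared is at or
#' below `flag_r2` are flagged for removal from downstream analyses.
#'
#' @param config A [sim_config()] object (`config$seed` controls the
#'   pedigree and all replicates).
#' @param n_simulations Number of gene-drop replicates (>= 2).
#' @param flag_r2 Flagging threshold for per-gamete adjusted R-squared.
#' @param span_sd SD multiplier of the span filter.
#' @return List with `per_simulation` (adjusted R-squared and slope per
#'   replicate), `per_gamete` (adjusted R-squared per gamete across
#'   replicates), `flagged_gametes`, `n_gametes` and the pedigree used.
#' @export
validation_run <- function(config, n_simulations, flag_r2 = 0.95, span_sd = 2.5) {
  stopifnot(inherits(config, "sim_config"))
  if (n_simulations < 2) stopf("n_simulations must be >= 2")
  base_seed <- config$seed %||% sample.int(.Machine$integer.max %/% 2L, 1L)
  cfg <- config
  cfg$seed <- base_seed
  ped <- simulate_pedigree(cfg)
  # marker set and population allele frequencies are fixed across replicates;
  # only meioses and genotypes are re-simulated
  snp_map <- simulate_snp_map(cfg)
  subp_template <- build_subpedigrees(ped, genotyped_ids = ped$id)
  if (nrow(subp_template) == 0)
    stopf("configuration yields no five-member subpedigrees; increase pedigree depth")

  per_sim <- vector("list", n_simulations)
  detected <- list(); truth_acc <- list()
  for (s in seq_len(n_simulations)) {
    cfg$seed <- base_seed + s
    gd <- gene_drop(ped, cfg, map = snp_map)
    qc <- mendelian_qc(subp_template, gd$panel)
    det <- detect_crossovers(qc$subpeds, qc$panel, span_sd = span_sd)
    acc <- det$acc
    cmp <- merge(acc[, c("gamete", "acc")],
                 gd$truth[, c("gamete", "acc_true")], by = "gamete")
    if (nrow(cmp) < 3)
      stopf("simulation %d: detection yielded %d informative gametes", s, nrow(cmp))
    fit <- summary(lm(acc ~ acc_true, data = cmp))
    per_sim[[s]] <- data.frame(simulation = s,
                               n_gametes = nrow(cmp),
                               adj_r_squared = fit$adj.r.squared,
                               slope = coef(fit)[2, 1],
                               mean_detected = mean(cmp$acc),
                               mean_true = mean(cmp$acc_true))
    detected[[s]] <- setNames(cmp$acc, cmp$gamete)
    truth_acc[[s]] <- setNames(cmp$acc_true, cmp$gamete)
    rm(gd, qc, det); gc(FALSE)
  }
  per_sim <- do.call(rbind, per_sim)

  gam_ids <- Reduce(intersect, lapply(detected, names))
  per_gam <- vapply(gam_ids, function(g) {
    d <- vapply(detected, `[[`, 0, g)
    t <- vapply(truth_acc, `[[`, 0, g)
    if (var(t) == 0) return(NA_real_)
    suppressWarnings(summary(lm(d ~ t))$adj.r.squared)
  }, 0)
  flagged <- gam_ids[!is.na(per_gam) & per_gam <= flag_r2]

  # per-simulation accuracy over the retained gametes (the per-gamete
  # exclusion is part of the QC design: gametes whose detection is
  # systematically unreliable are removed from the study)
  keep_ids <- setdiff(gam_ids, flagged)
  per_sim$adj_r_squared_retained <- vapply(seq_len(n_simulations), function(s) {
    d <- detected[[s]][keep_ids]; t <- truth_acc[[s]][keep_ids]
    summary(lm(d ~ t))$adj.r.squared
  }, 0)

  list(per_simulation = per_sim,
       per_gamete = data.frame(gamete = gam_ids, adj_r_squared = per_gam,
                               row.names = NULL),
       flagged_gametes = flagged,
       n_gametes = length(gam_ids),
       pedigree = ped)
}
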
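#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates the stages end-to-end on simulated data: pedigree and
#' gene-drop simulation, subpedigree construction, Mendelian QC, crossover
#' detection, linkage-map estimation, landscape binning, heritability, and
#' (optionally) GWAS. Returns a machine-readable manifest of per-stage
#' counts; when `out_dir` is given, stage outputs are written as TSV and
#' their MD5 checksums recorded.
#'
#' @param config A [sim_config()] object (its `seed` fixes all randomness).
#' @param stages Character vector of stages to run, a subset (in order) of
#'   `c("simulate", "subped", "detect", "map", "landscape", "h2", "gwas")`.
#' @param out_dir Optional output directory for TSV artefacts.
#' @param inputs Optional list with precomputed `pedigree` and `panel`
#'   (skips the simulate stage).
#' @return List of class `pipeline_manifest`: `seed`, `stages`, per-stage
#'   `counts`, `results` (in-memory stage outputs) and `checksums`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "subped", "detect", "map",
                                    "landscape", "h2"),
                         out_dir = NULL, inputs = NULL) {
  all_stages <- c("simulate", "subped", "detect", "map", "landscape", "h2", "gwas")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  counts <- list(); results <- list(); files <- character(0)
  emit <- function(obj, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(name, ".tsv"))
      data.table::fwrite(as.data.frame(obj), path, sep = "\t")
      files <<- c(files, path)
    }
  }

  if ("simulate" %in% stages) {
    ped <- simulate_pedigree(config)
    gd <- gene_drop(ped, config)
    panel <- gd$panel
    results$truth <- gd$truth
    counts$simulate <- list(n_individuals = nrow(ped),
                            n_snps = ncol(panel$geno),
                            n_gametes = nrow(gd$truth))
    emit(ped, "pedigree"); emit(gd$truth, "truth")
  } else {
    if (is.null(inputs$pedigree) || is.null(inputs$panel))
      stopf("without the simulate stage, supply inputs$pedigree and inputs$panel")
    ped <- inputs$pedigree; panel <- inputs$panel
  }
  results$pedigree <- ped; results$panel <- panel

  subp <- NULL
  if ("subped" %in% stages) {
    subp <- build_subpedigrees(ped, rownames(panel$geno))
    qc <- mendelian_qc(subp, panel)
    panel <- qc$panel; subp <- qc$subpeds
    counts$subped <- list(n_subpedigrees = nrow(subp),
                          n_discarded_duplicate = attr(subp, "n_discarded_duplicate"),
                          n_discarded_mismatch = qc$report$n_subpeds_discarded,
                          n_genotypes_masked = qc$report$n_genotypes_masked)
    results$subpeds <- subp
    emit(subp, "subpedigrees")
  }

  det <- NULL
  if ("detect" %in% stages) {
    if (is.null(subp)) stopf("detect requires the subped stage")
    det <- detect_crossovers(subp, panel)
    counts$detect <- list(n_gametes = nrow(det$acc),
                          n_crossovers = sum(det$acc$acc),
                          n_single_snp_removed = det$filter_stats$n_single_snp_removed,
                          n_span_runs_removed = det$filter_stats$span$n_runs_removed %||% 0L)
    results$acc <- det$acc; results$phase <- det$phase
    emit(det$acc, "crossover_table")
  }

  lmap <- NULL
  if ("map" %in% stages) {
    if (is.null(det)) stopf("map requires the detect stage")
    lmap <- build_map(det$phase)
    counts$map <- list(n_markers = nrow(lmap$map),
                       n_removed = length(lmap$removed),
                       total_cm_averaged =
                         sum(tapply(lmap$map$cM_averaged, lmap$map$chr, max)))
    results$linkage_map <- lmap
    emit(lmap$map, "linkage_map")
  }

  if ("landscape" %in% stages) {
    if (is.null(lmap)) stopf("landscape requires the map stage")
    lens <- config$chromosome_lengths_bp
    bins_m <- bin_crossover_probability(lmap$intervals_male, lens)
    bins_f <- bin_crossover_probability(lmap$intervals_female, lens)
    broad <- broadscale_regressions(chromosome_map_lengths(lmap$map, lens))
    counts$landscape <- list(n_bins = nrow(bins_m))
    results$bins_male <- bins_m; results$bins_female <- bins_f
    results$broadscale <- broad
    emit(bins_m, "bins_male"); emit(bins_f, "bins_female")
  }

  acc_tab <- NULL
  if (any(c("h2", "gwas") %in% stages)) {
    if (is.null(det)) stopf("h2/gwas require the detect stage")
    truth <- results$truth
    acc_tab <- det$acc
    sex_of <- setNames(ped$sex, as.character(ped$id))
    acc_tab$fid <- sub("->.*$", "", acc_tab$gamete)
    acc_tab$sex <- sex_of[acc_tab$fid]
  }

  if ("h2" %in% stages) {
    fids <- sort(unique(acc_tab$fid))
    grm <- compute_grm(panel, ids = fids, drop_monomorphic = TRUE)
    fit <- fit_animal_model(acc_tab$acc, acc_tab$fid,
                            fixed = data.frame(sex = acc_tab$sex),
                            relationship = grm,
                            pe = max(table(acc_tab$fid)) >= 2)
    counts$h2 <- list(h2 = fit$h2, h2_se = fit$h2_se, V_P = fit$V_P)
    results$h2_fit <- fit
  }

  if ("gwas" %in% stages) {
    nrm <- pedigree_nrm(ped)
    gw <- run_gwas(acc_tab, panel, nrm, stratum = "all")
    counts$gwas <- list(lambda = gw$lambda, n_eff = gw$n_eff,
                        threshold = gw$threshold,
                        top_p = min(gw$records$p))
    results$gwas <- gw
    emit(gw$records, "gwas_records")
  }

  checksums <- if (length(files)) tools::md5sum(files) else character(0)
  structure(list(seed = config$seed, stages = stages, counts = counts,
                 results = results, checksums = checksums),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline manifest (seed:", x$seed %||% "none", ")\n")
  for (s in names(x$counts)) {
    vals <- unlist(x$counts[[s]])
    cat(sprintf("  %-10s %s\n", s,
                paste(names(vals), signif(as.numeric(vals), 6),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}
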
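# Crossover calling and the two double-crossover QC filters.
#
# A crossover is a switch in grandparental origin between adjacent
# informative SNPs on one transmitted chromosome. Phasing errors manifest
# as spurious double crossovers, removed by (i) deleting internal origin
# runs of a single SNP and (ii) deleting internal runs whose physical span
# is an extreme outlier on the log10 scale.

#' Count crossovers in one origin vector
#'
#' @param origin Integer vector of grandparental origins along a
#'   chromosome (1 = paternal, 2 = maternal).
#' @return Number of adjacent positions with differing origin.
#' @export
call_crossovers <- function(origin) {
  origin <- origin[!is.na(origin)]
  if (length(origin) < 2L) return(0L)
  sum(diff(origin) != 0L)
}

# run-length view of one gamete-chromosome: returns data.frame of runs with
# start/end indices; internal = not first and not last run.
.origin_runs <- function(origin) {
  r <- rle(origin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(value = r$values, start = starts, end = ends,
             length = r$lengths,
             internal = seq_along(r$values) != 1L &
                        seq_along(r$values) != length(r$values))
}

#' Remove single-SNP origin runs
#'
#' An internal run of grandparental origin consisting of a single SNP
#' implies a double crossover on either side of that SNP and is treated as
#' a phasing error: the SNP is removed from the informative list. Terminal
#' runs (touching a chromosome end) are retained, since they are not
#' flanked by crossovers on both sides. The filter is applied once per
#' gamete-chromosome; runs are recomputed afterwards by downstream code.
#'
#' @param phase A `phase_set` from [phase_gametes()].
#' @return List with `phase` (filtered set) and `n_removed` (SNPs deleted).
#' @export
filter_single_snp_runs <- function(phase) {
  if (nrow(phase) == 0) return(list(phase = phase, n_removed = 0L))
  drop <- phase[, {
    runs <- .origin_runs(origin)
    bad <- runs[runs$internal & runs$length == 1L, , drop = FALSE]
    list(row = if (nrow(bad)) .I[bad$start] else integer(0))
  }, by = .(gamete, chr)]$row
  out <- if (length(drop)) phase[-drop] else phase
  attr(out, "n_conflict") <- attr(phase, "n_conflict")
  class(out) <- class(phase)
  list(phase = out, n_removed = length(drop))
}

#' Remove short-span double crossovers
#'
#' For every internal origin run (a double crossover: opposite origin on
#' both sides), the span distance is the bp distance between the informative
#' SNPs immediately flanking the run on the outside. The pooled mean and SD
#' of log10 span distance are computed across all gametes; runs with
#' log10 span below `mean - sd_threshold * SD` have all their SNPs removed.
#' Terminal runs are never filtered.
#'
#' @param phase A `phase_set`, after [filter_single_snp_runs()].
#' @param sd_threshold Number of SDs below the mean defining a short span.
#' @return List with `phase` (filtered), and `stats`: mean/sd of log10
#'   span, threshold, counts of double crossovers and removed runs.
#' @export
filter_short_double_crossovers <- function(phase, sd_threshold = 2.5) {
  empty_stats <- list(mean_log10_span = NA_real_, sd_log10_span = NA_real_,
                      threshold_log10 = NA_real_, n_double_crossovers = 0L,
                      n_runs_removed = 0L, n_snps_removed = 0L)
  if (nrow(phase) == 0) return(list(phase = phase, stats = empty_stats))

  runs <- phase[, {
    r <- .origin_runs(origin)
    r <- r[r$internal, , drop = FALSE]
    if (nrow(r)) {
      list(start = r$start, end = r$end,
           span = as.numeric(bp[pmin(r$end + 1L, .N)]) -
                  as.numeric(bp[pmax(r$start - 1L, 1L)]),
           first_row = .I[1])
    } else {
      list(start = integer(0), end = integer(0), span = numeric(0),
           first_row = integer(0))
    }
  }, by = .(gamete, chr)]

  if (nrow(runs) < 2L) {
    warnf("fewer than 2 double crossovers in the data; span filter skipped")
    return(list(phase = phase, stats = empty_stats))
  }
  lg <- log10(runs$span)
  mu <- mean(lg); s <- sd(lg)
  thr <- mu - sd_threshold * s
  bad <- which(lg < thr)
  drop_rows <- integer(0)
  if (length(bad)) {
    for (b in bad) {
      drop_rows <- c(drop_rows,
                     (runs$first_row[b] - 1L) + seq(runs$start[b], runs$end[b]))
    }
  }
  out <- if (length(drop_rows)) phase[-drop_rows] else phase
  attr(out, "n_conflict") <- attr(phase, "n_conflict")
  class(out) <- class(phase)
  list(phase = out,
       stats = list(mean_log10_span = mu, sd_log10_span = s,
                    threshold_log10 = thr,
                    n_double_crossovers = nrow(runs),
                    n_runs_removed = length(bad),
                    n_snps_removed = length(drop_rows)))
}

#' Summarise autosomal crossover counts per gamete
#'
#' Computes, for every gamete in a phased set, the autosomal crossover
#' count (ACC), per-chromosome crossover counts, the number of informative
#' SNPs and the informative genome length (sum over chromosomes of the
#' distance between first and last informative SNP).
#'
#' @param phase A `phase_set` (normally after both QC filters).
#' @return `data.frame` with one row per gamete: `gamete`, `fid_sex`,
#'   `acc`, `n_informative`, `informative_length_bp`, then one `chr_<k>`
#'   column per chromosome with that chromosome's crossover count.
#' @export
summarize_acc <- function(phase) {
  if (nrow(phase) == 0) {
    return(data.frame(gamete = character(), fid_sex = character(),
                      acc = integer(), n_informative = integer(),
                      informative_length_bp = numeric()))
  }
  per_chr <- phase[, .(xo = call_crossovers(origin), n_inf = .N,
                       len = max(bp) - min(bp), fid_sex = fid_sex[1]),
                   by = .(gamete, chr)]
  wide <- data.table::dcast(per_chr, gamete ~ chr, value.var = "xo", fill = 0L)
  data.table::setnames(wide, setdiff(names(wide), "gamete"),
                       paste0("chr_", setdiff(names(wide), "gamete")))
  tot <- per_chr[, .(acc = sum(xo), n_informative = sum(n_inf),
                     informative_length_bp = sum(as.numeric(len)),
                     fid_sex = fid_sex[1]), by = gamete]
  out <- merge(tot, wide, by = "gamete")
  as.data.frame(out)
}

#' Detect crossovers end-to-end for a set of subpedigrees
#'
#' Convenience wrapper chaining [phase_gametes()], the two QC filters and
#' [summarize_acc()].
#'
#' @param subpeds Subpedigree table.
#' @param panel A [genotype_panel()].
#' @param span_sd SD multiplier of the span filter.
#' @param span_filter Set `FALSE` to skip the span filter.
#' @return List with `acc` (the crossover table), `phase` (filtered phase
#'   set) and `filter_stats`.
#' @export
detect_crossovers <- function(subpeds, panel, span_sd = 2.5, span_filter = TRUE) {
  ph <- phase_gametes(subpeds, panel)
  f1 <- filter_single_snp_runs(ph)
  if (span_filter) {
    f2 <- filter_short_double_crossovers(f1$phase, sd_threshold = span_sd)
  } else {
    f2 <- list(phase = f1$phase, stats = NULL)
  }
  list(acc = summarize_acc(f2$phase), phase = f2$phase,
       filter_stats = list(n_single_snp_removed = f1$n_removed,
                           span = f2$stats))
}
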
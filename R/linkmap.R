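# Two-point linkage-map estimation from phase-known gametes.
#
# With grandparental origin known at informative SNPs, the recombination
# fraction of an adjacent marker interval is estimated by counting, among
# gametes informative at both markers, those whose origin differs at the
# two ends. Map positions accumulate Kosambi centimorgans along each
# chromosome.

#' Kosambi map functions
#'
#' `kosambi_cm()` converts a recombination fraction to Kosambi
#' centimorgans, `d = 25 * ln((1 + 2r) / (1 - 2r))`; `kosambi_r()` is the
#' inverse.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param cm Map distance(s) in centimorgans.
#' @return Numeric vector.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) stopf("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(cm) {
  if (any(cm < 0, na.rm = TRUE)) stopf("cM must be >= 0")
  x <- exp(cm / 25)
  (x - 1) / (2 * (x + 1))
}

#' Adjacent-interval recombination fractions from phased gametes
#'
#' @param phase A `phase_set` from [phase_gametes()] (after QC filters).
#' @param map Marker map `data.frame` (`snp`, `chr`, `bp`) defining the
#'   genome order; defaults to the markers present in `phase`.
#' @param sex One of `"averaged"` (all gametes), `"male"`, `"female"`.
#' @param min_pairs Intervals covered by fewer informative gametes than
#'   this are treated as unestimable (`r = NA`, bridged downstream);
#'   default 1.
#' @return `data.frame` with one row per adjacent marker interval:
#'   `chr`, `left_snp`, `right_snp`, `left_bp`, `right_bp`, `r`,
#'   `n_informative_pairs`. Intervals with no informative gamete have
#'   `r = NA`. Estimates of 0.5 or more are truncated to 0.4999 with a
#'   warning.
#' @export
estimate_interval_rf <- function(phase, map = NULL,
                                 sex = c("averaged", "male", "female"),
                                 min_pairs = 1L) {
  sex <- match.arg(sex)
  ph <- data.table::copy(phase)
  if (sex == "male") ph <- ph[fid_sex == "M"]
  if (sex == "female") ph <- ph[fid_sex == "F"]
  if (is.null(map)) {
    map <- unique(as.data.frame(phase[, .(snp, chr, bp)]))
    map <- map[order(map$chr, map$bp), ]
  }
  map <- map[order(map$chr, map$bp), c("snp", "chr", "bp")]
  pos <- setNames(seq_len(nrow(map)), map$snp)

  # order markers within gamete by genome position, take adjacent-in-gamete
  # pairs that are also adjacent in the genome-order marker list
  ph <- ph[snp %in% map$snp]
  ph[, gpos := pos[snp]]
  data.table::setorder(ph, gamete, chr, gpos)
  pairs <- ph[, {
    if (.N >= 2L) {
      list(left = gpos[-.N], disc = diff(origin) != 0L, gap = diff(gpos))
    } else list(left = integer(0), disc = logical(0), gap = integer(0))
  }, by = .(gamete, chr)]
  pairs <- pairs[gap == 1L]  # strictly adjacent markers in genome order

  counts <- pairs[, .(n = .N, n_disc = sum(disc)), by = left]
  out <- data.frame(chr = map$chr[-nrow(map)],
                    left_snp = map$snp[-nrow(map)],
                    right_snp = map$snp[-1],
                    left_bp = map$bp[-nrow(map)],
                    right_bp = map$bp[-1],
                    stringsAsFactors = FALSE)
  out <- out[out$chr == map$chr[-1], , drop = FALSE]  # drop cross-chromosome rows
  key <- match(match(out$left_snp, map$snp), counts$left)
  out$n_informative_pairs <- ifelse(is.na(key), 0L, counts$n[key])
  out$r <- ifelse(is.na(key), NA_real_, counts$n_disc[key] / counts$n[key])
  out$r[out$n_informative_pairs < min_pairs] <- NA_real_
  if (any(!is.na(out$r) & out$r >= 0.5)) {
    warnf("%d interval estimates >= 0.5 truncated to 0.4999",
          sum(out$r >= 0.5, na.rm = TRUE))
    out$r[!is.na(out$r) & out$r >= 0.5] <- 0.4999
  }
  out$sex <- sex
  out
}

#' Build sex-specific Kosambi linkage maps with iterative marker QC
#'
#' Estimates adjacent-interval recombination fractions, converts them to
#' Kosambi cM and accumulates positions along each chromosome for the
#' sex-averaged, male and female strata. Markers whose sex-averaged map
#' distance to *both* adjacent markers exceeds `max_cm` are assumed to be
#' incorrectly mapped and removed, and estimation is rerun until no such
#' marker remains (chromosome-terminal markers, having one neighbour, are
#' exempt). Intervals with no informative gametes contribute 0 cM and are
#' flagged.
#'
#' @param phase A `phase_set` after QC filters.
#' @param map Marker map defining genome order (default: markers in
#'   `phase`).
#' @param max_cm Removal threshold in cM (default 3).
#' @param min_pairs Passed to [estimate_interval_rf()]: minimum informative
#'   gametes per interval before it is bridged instead of estimated.
#' @param max_iter Safety cap on QC iterations.
#' @return List with `map` (per-marker `chr`, `bp`, `cM_averaged`,
#'   `cM_male`, `cM_female`), `removed` (marker ids removed by QC),
#'   `intervals` (final sex-averaged intervals) and `n_bridged`
#'   (zero-information intervals bridged with 0 cM).
#' @export
build_map <- function(phase, map = NULL, max_cm = 3, min_pairs = 1L,
                      max_iter = 50L) {
  if (is.null(map)) {
    map <- unique(as.data.frame(phase[, .(snp, chr, bp)]))
    map <- map[order(map$chr, map$bp), ]
  }
  cur <- map
  removed <- character(0)
  for (it in seq_len(max_iter)) {
    iv <- estimate_interval_rf(phase, cur, sex = "averaged", min_pairs = min_pairs)
    d <- ifelse(is.na(iv$r), 0, kosambi_cm(iv$r))
    # distance of each marker to its left/right neighbour (NA at ends)
    mk <- cur
    left_d <- d[match(mk$snp, iv$right_snp)]
    right_d <- d[match(mk$snp, iv$left_snp)]
    bad <- !is.na(left_d) & !is.na(right_d) & left_d > max_cm & right_d > max_cm
    if (!any(bad)) break
    removed <- c(removed, mk$snp[bad])
    cur <- cur[!bad, , drop = FALSE]
    nchr <- table(cur$chr)
    if (any(nchr < 2)) stopf("marker QC reduced a chromosome below 2 markers")
  }
  strata <- list(averaged = "averaged", male = "male", female = "female")
  ivs <- lapply(strata, function(s)
    estimate_interval_rf(phase, cur, sex = s, min_pairs = min_pairs))
  n_bridged <- sum(is.na(ivs$averaged$r))
  out <- cur[order(cur$chr, cur$bp), c("snp", "chr", "bp")]
  rownames(out) <- NULL
  for (s in names(strata)) {
    iv <- ivs[[s]]
    cm <- numeric(nrow(out))
    for (cc in unique(out$chr)) {
      rows <- which(out$chr == cc)
      ivc <- iv[iv$chr == cc, , drop = FALSE]
      if (nrow(ivc) != length(rows) - 1L)
        stopf("internal error: interval/marker mismatch on chromosome %s", cc)
      d <- ifelse(is.na(ivc$r), 0, kosambi_cm(ivc$r))
      cm[rows] <- cumsum(c(0, d))
    }
    out[[paste0("cM_", s)]] <- cm
  }
  list(map = out, removed = removed, intervals = ivs$averaged,
       intervals_male = ivs$male, intervals_female = ivs$female,
       n_bridged = n_bridged)
}
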
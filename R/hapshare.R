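# Haplotype sharing around a focal SNP: core haplotypes perfectly tagging
# a focal allele, and the bp distance over which carriers in two
# populations remain identical downstream of the core.

#' Phased haplotype set
#'
#' @param haplotypes Matrix of 0/1 alleles, haplotypes x SNPs, SNPs in
#'   genome order.
#' @param bp Base-pair positions per SNP (strictly increasing).
#' @param population Population label.
#' @return Object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, bp, population = "pop") {
  if (ncol(haplotypes) != length(bp)) stopf("bp length must match SNP count")
  if (any(diff(bp) <= 0)) stopf("bp must be strictly increasing")
  if (!all(haplotypes %in% 0:1)) stopf("haplotypes must be biallelic 0/1")
  structure(list(H = as.matrix(haplotypes), bp = as.numeric(bp),
                 population = population), class = "haplotype_set")
}

#' Core haplotypes perfectly tagging a focal allele
#'
#' Enumerates the distinct haplotypes over a window of `core_length` SNPs
#' adjacent to the focal SNP (by default the SNPs immediately on its
#' proximal side) and returns those whose carriers all bear the same
#' allele at the focal SNP (tagging purity 1).
#'
#' @param set A [haplotype_set()].
#' @param focal_idx Column index of the focal SNP.
#' @param core_length Number of SNPs in the core (default 6).
#' @param side `"proximal"` (lower indices, default) or `"distal"` window
#'   placement relative to the focal SNP.
#' @return `data.frame` with `core` (allele string), `start_idx`,
#'   `end_idx`, `tagged_allele`, `n_carriers`; zero rows (with a message
#'   attribute) when no perfectly tagging haplotype exists.
#' @export
find_core_haplotypes <- function(set, focal_idx, core_length = 6L,
                                 side = c("proximal", "distal")) {
  side <- match.arg(side)
  m <- ncol(set$H)
  if (focal_idx < 1 || focal_idx > m) stopf("focal SNP outside region")
  idx <- if (side == "proximal") (focal_idx - core_length):(focal_idx - 1L)
         else (focal_idx + 1L):(focal_idx + core_length)
  if (any(idx < 1 | idx > m))
    stopf("core window of %d SNPs does not fit on the %s side", core_length, side)
  cores <- apply(set$H[, idx, drop = FALSE], 1, paste, collapse = "")
  focal <- set$H[, focal_idx]
  out <- list()
  for (cr in unique(cores)) {
    alleles <- unique(focal[cores == cr])
    if (length(alleles) == 1L) {
      out[[cr]] <- data.frame(core = cr, start_idx = idx[1],
                              end_idx = idx[length(idx)],
                              tagged_allele = alleles,
                              n_carriers = sum(cores == cr),
                              stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(core = character(), start_idx = integer(), end_idx = integer(),
               tagged_allele = integer(), n_carriers = integer())
  rownames(res) <- NULL
  if (!nrow(res))
    attr(res, "message") <- sprintf("no haplotype of %d SNPs perfectly tags the focal SNP",
                                    core_length)
  res
}

#' Haplotype-sharing distance between two populations
#'
#' For one core haplotype, extracts all carriers in the focal and the
#' reference set and, for every cross-population pair, records the bp
#' distance from the core to the first mismatching SNP downstream. Pairs
#' identical up to the end of the region are censored at the distance to
#' the last compared SNP.
#'
#' @param core One row of [find_core_haplotypes()] (or a core string plus
#'   `start_idx`/`end_idx`).
#' @param focal_set,reference_set [haplotype_set()] objects over the same
#'   SNPs.
#' @param direction `"downstream"` walks towards higher bp from the core
#'   end (default); `"upstream"` towards lower bp from the core start.
#' @return List with `mean_bp`, `sd_bp` (over uncensored pairs), `n_pairs`,
#'   `n_censored`, `mean_bp_all` (censored included) and the per-pair
#'   distances.
#' @export
haplotype_sharing_length <- function(core, focal_set, reference_set,
                                     direction = c("downstream", "upstream")) {
  direction <- match.arg(direction)
  if (!identical(focal_set$bp, reference_set$bp))
    stopf("focal and reference sets must cover the same SNPs")
  bp <- focal_set$bp
  idx <- core$start_idx:core$end_idx
  carriers <- function(set) {
    cr <- apply(set$H[, idx, drop = FALSE], 1, paste, collapse = "")
    which(cr == core$core)
  }
  cf <- carriers(focal_set); cr <- carriers(reference_set)
  if (!length(cf) || !length(cr)) {
    return(list(mean_bp = NA_real_, sd_bp = NA_real_, n_pairs = 0L,
                n_censored = 0L, mean_bp_all = NA_real_, distances = numeric(0)))
  }
  if (direction == "downstream") {
    walk <- (core$end_idx + 1L):ncol(focal_set$H)
    origin <- bp[core$end_idx]
    if (core$end_idx >= ncol(focal_set$H)) walk <- integer(0)
  } else {
    walk <- rev(seq_len(core$start_idx - 1L))
    origin <- bp[core$start_idx]
    if (core$start_idx <= 1L) walk <- integer(0)
  }
  dist <- numeric(0); cens <- logical(0)
  for (i in cf) {
    for (j in cr) {
      if (!length(walk)) { dist <- c(dist, 0); cens <- c(cens, TRUE); next }
      mism <- which(focal_set$H[i, walk] != reference_set$H[j, walk])
      if (length(mism)) {
        dist <- c(dist, abs(bp[walk[mism[1]]] - origin))
        cens <- c(cens, FALSE)
      } else {
        dist <- c(dist, abs(bp[walk[length(walk)]] - origin))
        cens <- c(cens, TRUE)
      }
    }
  }
  unc <- dist[!cens]
  list(mean_bp = if (length(unc)) mean(unc) else NA_real_,
       sd_bp = if (length(unc) > 1) sd(unc) else NA_real_,
       n_pairs = length(dist), n_censored = sum(cens),
       mean_bp_all = mean(dist),
       distances = data.frame(distance_bp = dist, censored = cens))
}
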
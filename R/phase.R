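# Single-locus phasing of the gamete transmitted from the FID to its
# offspring. All functions are vectorised over markers; genotype calls
# count copies of allele B (0, 1, 2, NA).

#' Allele transmitted from the FID to the offspring at one locus
#'
#' Determines which allele the focal individual passed to the offspring
#' using only the three single-locus genotypes: a homozygous offspring
#' received that allele; a heterozygous offspring with a homozygous mate
#' received the allele the mate could not have given. The result must be
#' carried by the FID, otherwise it is undetermined.
#'
#' @param fid_call,offspring_call,mate_call Genotype vectors (0/1/2/NA).
#' @return Integer vector: 0 (allele A), 1 (allele B) or `NA`
#'   (undetermined).
#' @export
transmitted_allele <- function(fid_call, offspring_call, mate_call) {
  n <- max(length(fid_call), length(offspring_call), length(mate_call))
  fid <- rep_len(fid_call, n); off <- rep_len(offspring_call, n)
  mate <- rep_len(mate_call, n)
  tr <- rep(NA_integer_, n)
  tr[!is.na(off) & off == 0L] <- 0L
  tr[!is.na(off) & off == 2L] <- 1L
  het <- !is.na(off) & off == 1L & !is.na(mate)
  tr[het & mate == 0L] <- 1L  # mate gave A, FID gave B
  tr[het & mate == 2L] <- 0L
  # FID must carry the transmitted allele
  carries <- !is.na(tr) & !is.na(fid) &
    ((tr == 0L & fid <= 1L) | (tr == 1L & fid >= 1L))
  tr[!carries] <- NA_integer_
  tr
}

#' Grandparental origin of the transmitted allele
#'
#' A marker is informative only when the FID is heterozygous and exactly one
#' of the two possible grandparental assignments (transmitted allele from
#' the FID's father vs. mother) is consistent with the FID's parents'
#' genotypes. A missing parent genotype is compatible with either allele.
#'
#' @param fid_call Genotypes of the FID (0/1/2/NA).
#' @param transmitted Transmitted allele from [transmitted_allele()].
#' @param father_call,mother_call Genotypes of the FID's parents.
#' @return Integer vector: 1 = paternal, 2 = maternal, `NA` = unknown.
#'   Residual Mendelian conflicts (neither assignment consistent) are `NA`
#'   with attribute `conflict` marking them.
#' @export
grandparental_origin <- function(fid_call, transmitted, father_call, mother_call) {
  n <- max(length(fid_call), length(transmitted),
           length(father_call), length(mother_call))
  fid <- rep_len(fid_call, n); tr <- rep_len(transmitted, n)
  fa <- rep_len(father_call, n); mo <- rep_len(mother_call, n)

  carries <- function(g, a) is.na(g) | (a == 0L & g <= 1L) | (a == 1L & g >= 1L)
  other <- 1L - tr
  ok <- !is.na(tr) & !is.na(fid) & fid == 1L
  pat_ok <- ok & carries(fa, tr) & carries(mo, other)
  mat_ok <- ok & carries(mo, tr) & carries(fa, other)

  origin <- rep(NA_integer_, n)
  origin[pat_ok & !mat_ok] <- 1L
  origin[mat_ok & !pat_ok] <- 2L
  conflict <- ok & !pat_ok & !mat_ok
  attr(origin, "conflict") <- conflict
  origin
}

#' Phase all gametes of a set of subpedigrees
#'
#' Applies [transmitted_allele()] and [grandparental_origin()] across all
#' markers for every subpedigree, returning the grandparental-origin
#' vectors over informative SNPs: the raw material for crossover calling.
#'
#' @param subpeds Subpedigree table from [build_subpedigrees()].
#' @param panel A [genotype_panel()] containing all members.
#' @return A `phase_set`: `data.table` with columns `gamete`, `fid_sex`,
#'   `chr`, `snp`, `bp`, `origin` (1 = paternal, 2 = maternal), ordered by
#'   gamete, chromosome and bp; the number of residual single-locus
#'   conflicts is in attribute `n_conflict`.
#' @export
phase_gametes <- function(subpeds, panel) {
  G <- panel$geno
  map <- panel$map
  n_conflict <- 0L
  out <- vector("list", nrow(subpeds))
  for (i in seq_len(nrow(subpeds))) {
    s <- subpeds[i, ]
    tr <- transmitted_allele(G[s$fid, ], G[s$offspring, ], G[s$mate, ])
    orig <- grandparental_origin(G[s$fid, ], tr, G[s$father, ], G[s$mother, ])
    n_conflict <- n_conflict + sum(attr(orig, "conflict"))
    keep <- which(!is.na(orig))
    if (!length(keep)) next
    out[[i]] <- data.table::data.table(
      gamete = s$gamete, fid_sex = s$fid_sex,
      chr = map$chr[keep], snp = map$snp[keep], bp = map$bp[keep],
      origin = as.integer(orig[keep]))
  }
  ph <- data.table::rbindlist(out)
  if (nrow(ph)) data.table::setorder(ph, gamete, chr, bp)
  attr(ph, "n_conflict") <- n_conflict
  class(ph) <- c("phase_set", class(ph))
  ph
}
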
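#' Construct five-member subpedigrees for crossover phasing
#'
#' For every parent-offspring pair in the pedigree, a subpedigree is formed
#' containing the focal individual (FID, the parent in which the scored
#' meiosis occurred), both of the FID's parents, the offspring, and the
#' offspring's other parent (mate). A pair is retained only when all five
#' individuals are genotyped and distinct; subpedigrees that would include
#' the same individual twice (e.g. father-daughter matings) are discarded
#' and counted.
#'
#' @param pedigree Pedigree `data.frame` (`id`, `sire`, `dam`, `sex`).
#' @param genotyped_ids Character vector of genotyped individual ids.
#' @return A `data.frame` of subpedigrees (`fid`, `offspring`, `father`,
#'   `mother`, `mate`, `fid_sex`, `gamete`), with the number of discarded
#'   duplicate-member pairs in attribute `n_discarded_duplicate`.
#' @export
build_subpedigrees <- function(pedigree, genotyped_ids) {
  ped <- pedigree
  genotyped_ids <- as.character(genotyped_ids)
  idx <- match(ped$id, ped$id)  # identity; lookup below by match on id
  get <- function(ids, col) ped[[col]][match(ids, ped$id)]

  rows <- list()
  n_dup <- 0L
  off <- ped[!is.na(ped$sire) & !is.na(ped$dam), , drop = FALSE]
  for (side in c("sire", "dam")) {
    fid <- as.character(off[[side]])
    mate <- as.character(off[[if (side == "sire") "dam" else "sire"]])
    father <- as.character(get(fid, "sire"))
    mother <- as.character(get(fid, "dam"))
    d <- data.frame(fid = fid, offspring = as.character(off$id),
                    father = father, mother = mother, mate = mate,
                    fid_sex = if (side == "sire") "M" else "F",
                    stringsAsFactors = FALSE)
    # FID's parents must be known
    d <- d[!is.na(d$father) & !is.na(d$mother), , drop = FALSE]
    if (nrow(d) == 0) next
    members <- d[, c("fid", "offspring", "father", "mother", "mate")]
    all_genod <- apply(members, 1, function(r) all(r %in% genotyped_ids))
    d <- d[all_genod, , drop = FALSE]
    if (nrow(d) == 0) next
    distinct <- apply(d[, c("fid", "offspring", "father", "mother", "mate")], 1,
                      function(r) !anyDuplicated(r))
    n_dup <- n_dup + sum(!distinct)
    d <- d[distinct, , drop = FALSE]
    rows[[side]] <- d
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fid = character(), offspring = character(),
                      father = character(), mother = character(),
                      mate = character(), fid_sex = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out$gamete <- if (nrow(out)) gamete_id(out$fid, out$offspring) else character(0)
  attr(out, "n_discarded_duplicate") <- n_dup
  out
}

#' Mendelian-consistency quality control of subpedigrees
#'
#' For every parent-offspring pair inside each subpedigree (FID-father,
#' FID-mother, offspring-FID, offspring-mate) and every marker, genotype
#' pairs sharing no allele (opposing homozygotes, 0 vs 2) are set missing in
#' both individuals. Subpedigrees containing a parent-offspring pair whose
#' pre-masking mismatch rate exceeds `mismatch_threshold` (computed over
#' markers where both calls are non-missing) are discarded.
#'
#' @param subpeds Output of [build_subpedigrees()].
#' @param panel A [genotype_panel()] covering all subpedigree members.
#' @param mismatch_threshold Maximum tolerated proportion of mismatching
#'   loci in a parent-offspring pair (default 0.001, i.e. 0.1%).
#' @return List with elements `panel` (masked copy), `subpeds` (retained
#'   rows) and `report` (per-pair mismatch counts and rates).
#' @export
mendelian_qc <- function(subpeds, panel, mismatch_threshold = 0.001) {
  G <- panel$geno
  members <- unique(unlist(subpeds[, c("fid", "offspring", "father", "mother", "mate")]))
  missing <- setdiff(members, rownames(G))
  if (length(missing))
    stopf("individuals absent from panel: %s", paste(head(missing, 5), collapse = ", "))

  pairs <- unique(rbind(
    data.frame(parent = subpeds$father, child = subpeds$fid),
    data.frame(parent = subpeds$mother, child = subpeds$fid),
    data.frame(parent = subpeds$fid, child = subpeds$offspring),
    data.frame(parent = subpeds$mate, child = subpeds$offspring)
  ))
  if (nrow(pairs)) {
    gp <- G[pairs$parent, , drop = FALSE]
    gc <- G[pairs$child, , drop = FALSE]
    conflict <- !is.na(gp) & !is.na(gc) & abs(gp - gc) == 2L
    comparable <- rowSums(!is.na(gp) & !is.na(gc))
    n_mis <- rowSums(conflict)
    pairs$n_compared <- comparable
    pairs$n_mismatch <- n_mis
    pairs$rate <- ifelse(comparable > 0, n_mis / comparable, 0)
    # mask conflicting genotypes in both members
    for (i in which(n_mis > 0)) {
      cols <- which(conflict[i, ])
      G[pairs$parent[i], cols] <- NA_integer_
      G[pairs$child[i], cols] <- NA_integer_
    }
  } else {
    pairs$n_compared <- integer(0); pairs$n_mismatch <- integer(0); pairs$rate <- numeric(0)
  }

  bad_pairs <- pairs[pairs$rate > mismatch_threshold, , drop = FALSE]
  bad_key <- paste(bad_pairs$parent, bad_pairs$child)
  sub_bad <- rep(FALSE, nrow(subpeds))
  for (cols in list(c("father", "fid"), c("mother", "fid"),
                    c("fid", "offspring"), c("mate", "offspring"))) {
    sub_bad <- sub_bad | (paste(subpeds[[cols[1]]], subpeds[[cols[2]]]) %in% bad_key)
  }
  retained <- subpeds[!sub_bad, , drop = FALSE]
  attr(retained, "n_discarded_duplicate") <- attr(subpeds, "n_discarded_duplicate")

  masked <- genotype_panel(panel$map, G)
  list(panel = masked, subpeds = retained,
       report = list(pairs = pairs,
                     n_subpeds_discarded = sum(sub_bad),
                     n_genotypes_masked = sum(pairs$n_mismatch) * 2L))
}
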
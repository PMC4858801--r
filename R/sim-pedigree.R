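#' Simulate a multi-generation pedigree
#'
#' Generation 0 consists of unrelated founders with balanced sexes. In each
#' later generation, males and females of the previous generation are paired
#' monogamously at random and each pair produces a litter, so parents have
#' repeated offspring and individuals of intermediate generations qualify as
#' focal individuals (FIDs) whose own parents are genotyped.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `id`, `sire`, `dam` (NA for
#'   founders), `sex` (`"M"`/`"F"`) and `generation`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$n_founders < 2 || config$n_generations < 1)
    stopf("need n_founders >= 2 and n_generations >= 1")

  balanced_sexes <- function(n) sample(rep(c("M", "F"), length.out = n))

  ped <- data.frame(id = seq_len(config$n_founders),
                    sire = NA_integer_, dam = NA_integer_,
                    sex = balanced_sexes(config$n_founders),
                    generation = 0L, stringsAsFactors = FALSE)
  next_id <- config$n_founders + 1L
  opp <- rep_len(config$offspring_per_pair, max(1L, config$n_generations - 1L))

  for (g in seq_len(config$n_generations - 1L)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- sample(prev$id[prev$sex == "M"])
    females <- sample(prev$id[prev$sex == "F"])
    n_pairs <- min(length(males), length(females))
    if (n_pairs == 0L)
      stopf("generation %d has no possible matings (all one sex)", g)
    rows <- list()
    for (k in seq_len(n_pairs)) {
      n_off <- if (config$offspring_dist == "poisson") rpois(1L, opp[g]) else round(opp[g])
      if (n_off <= 0) next
      ids <- next_id:(next_id + n_off - 1L)
      next_id <- next_id + n_off
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids, sire = males[k], dam = females[k],
        sex = balanced_sexes(n_off), generation = g,
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
      stopf("generation %d produced no offspring; increase offspring_per_pair", g)
    ped <- rbind(ped, do.call(rbind, rows))
  }
  ped
}

#' Validate a pedigree table
#'
#' Checks structural invariants: ids unique, parents present when stated,
#' parent sexes consistent with their role, and no individual its own
#' ancestor.
#'
#' @param ped Pedigree `data.frame` with columns `id`, `sire`, `dam`, `sex`.
#' @return The pedigree, invisibly, ordered so parents precede offspring.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(ped))) stopf("pedigree needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(ped$id)) stopf("duplicated ids in pedigree")
  known <- ped$id
  for (col in c("sire", "dam")) {
    miss <- !is.na(ped[[col]]) & !(ped[[col]] %in% known)
    if (any(miss)) stopf("%s of %s not in pedigree", col, ped$id[which(miss)[1]])
  }
  sex_of <- setNames(ped$sex, ped$id)
  bad_sire <- !is.na(ped$sire) & !is.na(sex_of[as.character(ped$sire)]) &
    sex_of[as.character(ped$sire)] == "F"
  bad_dam <- !is.na(ped$dam) & !is.na(sex_of[as.character(ped$dam)]) &
    sex_of[as.character(ped$dam)] == "M"
  if (any(bad_sire, na.rm = TRUE)) stopf("female individual recorded as sire")
  if (any(bad_dam, na.rm = TRUE)) stopf("male individual recorded as dam")
  ord <- pedigree_order(ped)
  ped[ord, , drop = FALSE]
}

# Topological order: parents before offspring. Errors on cycles
# (an individual that is its own ancestor).
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  depth <- rep(NA_integer_, n)
  resolve <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (seen[i]) stopf("pedigree cycle: individual %s is its own ancestor", ped$id[i])
    seen[i] <- TRUE
    s <- ped$sire[i]; d <- ped$dam[i]
    ds <- if (is.na(s)) -1L else resolve(idx[[as.character(s)]], seen)
    dd <- if (is.na(d)) -1L else resolve(idx[[as.character(d)]], seen)
    depth[i] <<- max(ds, dd) + 1L
    depth[i]
  }
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) resolve(i, seen)
  order(depth)
}
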
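#' SNP genotype panel
#'
#' Container for a marker map plus a genotype matrix. Genotype calls count
#' copies of allele B (0, 1, 2, `NA`).
#'
#' @param map `data.frame` with columns `snp`, `chr`, `bp` (and optionally
#'   `freq`, `allele_A`, `allele_B`). Markers must be ordered by chromosome
#'   and non-decreasing bp within chromosome.
#' @param geno Integer matrix, individuals x markers, rownames = individual
#'   ids, colnames = SNP ids matching `map$snp`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(map, geno) {
  need <- c("snp", "chr", "bp")
  if (!all(need %in% names(map))) stopf("map needs columns: %s", paste(need, collapse = ", "))
  if (is.null(rownames(geno))) stopf("geno must have individual ids as rownames")
  if (ncol(geno) != nrow(map)) stopf("geno has %d columns but map %d markers", ncol(geno), nrow(map))
  if (!identical(colnames(geno), map$snp)) colnames(geno) <- map$snp
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stopf("genotype calls must be 0, 1, 2 or NA")
  unord <- tapply(map$bp, map$chr, function(b) any(diff(b) < 0))
  if (any(unlist(unord))) stopf("bp must be non-decreasing within chromosome")
  structure(list(map = map, geno = geno), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs on %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}

#' Observed allele frequencies of a panel
#'
#' @param panel A [genotype_panel()].
#' @param ids Optional subset of individual ids.
#' @return Numeric vector of allele-B frequencies per marker.
#' @export
panel_freq <- function(panel, ids = NULL) {
  G <- panel$geno
  if (!is.null(ids)) G <- G[as.character(ids), , drop = FALSE]
  colMeans(G, na.rm = TRUE) / 2
}

# ---- flat-file interchange -------------------------------------------------

#' Read / write pedigree and genotype tables
#'
#' Pedigrees are TSV with columns `id`, `sire`, `dam`, `sex` (`M`/`F`,
#' missing parents `NA` or `0`). Genotypes travel either as a TSV matrix
#' (first column `id`, then one column per SNP) plus a marker-map TSV, or in
#' PLINK PED/MAP text format with alleles coded `A`/`B` and missing `0`.
#'
#' @param path,prefix File path (or path prefix for PED/MAP pairs).
#' @param ped Pedigree `data.frame`.
#' @param panel A [genotype_panel()].
#' @return Readers return the parsed object; writers return the path(s)
#'   invisibly.
#' @name pedrecomb-io
NULL

#' @rdname pedrecomb-io
#' @export
read_pedigree <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  for (col in c("sire", "dam")) {
    v <- d[[col]]
    v[v %in% c("0", 0)] <- NA
    d[[col]] <- v
  }
  validate_pedigree(d)
}

#' @rdname pedrecomb-io
#' @export
write_pedigree <- function(ped, path) {
  data.table::fwrite(ped, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname pedrecomb-io
#' @export
write_genotypes_tsv <- function(panel, prefix) {
  gpath <- paste0(prefix, "_geno.tsv")
  mpath <- paste0(prefix, "_map.tsv")
  g <- data.table::data.table(id = rownames(panel$geno))
  g <- cbind(g, as.data.table(panel$geno))
  data.table::fwrite(g, gpath, sep = "\t", na = "NA")
  data.table::fwrite(panel$map, mpath, sep = "\t", na = "NA")
  invisible(c(geno = gpath, map = mpath))
}

#' @rdname pedrecomb-io
#' @export
read_genotypes_tsv <- function(prefix) {
  g <- data.table::fread(paste0(prefix, "_geno.tsv"))
  map <- as.data.frame(data.table::fread(paste0(prefix, "_map.tsv")))
  ids <- as.character(g[[1]])
  G <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  genotype_panel(map, G)
}

#' @rdname pedrecomb-io
#' @export
write_plink <- function(panel, prefix, pedigree = NULL) {
  map <- panel$map
  mp <- data.frame(chr = map$chr, snp = map$snp, cm = 0, bp = map$bp)
  data.table::fwrite(mp, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  G <- panel$geno
  ids <- rownames(G)
  a1 <- matrix("A", nrow(G), ncol(G)); a2 <- matrix("B", nrow(G), ncol(G))
  a1[G >= 1] <- "B"; a2[G == 0 | G == 1] <- "A"
  a2[G == 1] <- "A"; a1[G == 1] <- "B"
  a1[is.na(G)] <- "0"; a2[is.na(G)] <- "0"
  inter <- matrix("", nrow(G), 2 * ncol(G))
  inter[, seq(1, 2 * ncol(G), 2)] <- a1
  inter[, seq(2, 2 * ncol(G), 2)] <- a2
  fam <- if (!is.null(pedigree)) {
    p <- pedigree[match(ids, as.character(pedigree$id)), ]
    data.frame(fam = 1, id = ids,
               sire = ifelse(is.na(p$sire), 0, p$sire),
               dam = ifelse(is.na(p$dam), 0, p$dam),
               sex = ifelse(is.na(p$sex), 0, ifelse(p$sex == "M", 1, 2)),
               pheno = -9)
  } else {
    data.frame(fam = 1, id = ids, sire = 0, dam = 0, sex = 0, pheno = -9)
  }
  out <- cbind(fam, as.data.frame(inter, stringsAsFactors = FALSE))
  data.table::fwrite(out, paste0(prefix, ".ped"), sep = " ", col.names = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' @rdname pedrecomb-io
#' @export
read_plink <- function(prefix) {
  mp <- as.data.frame(data.table::fread(paste0(prefix, ".map"),
                                        col.names = c("chr", "snp", "cm", "bp")))
  pd <- as.data.frame(data.table::fread(paste0(prefix, ".ped"), colClasses = "character"))
  ids <- pd[[2]]
  al <- as.matrix(pd[, -(1:6), drop = FALSE])
  m <- ncol(al) / 2
  a1 <- al[, seq(1, 2 * m, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, 2), drop = FALSE]
  G <- (a1 == "B") + (a2 == "B")
  G[a1 == "0" | a2 == "0"] <- NA
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  genotype_panel(data.frame(snp = mp$snp, chr = mp$chr, bp = mp$bp), G)
}
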
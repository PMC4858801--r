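# Relatedness matrices: genomic (GRM) and pedigree (numerator, NRM).

#' Genomic relatedness matrix with genomic inbreeding on the diagonal
#'
#' Off-diagonal elements are the marker average of
#' `(x_j - 2p)(x_k - 2p) / (2p(1-p))`; diagonal elements are `1 + F` where
#' `F` is the genomic inbreeding measure
#' `mean[(x^2 - (1 + 2p) x + 2 p^2) / (2p(1-p))]`. Allele frequencies are
#' estimated from the individuals supplied (or given). With
#' `adjust = TRUE`, off-diagonal values are shrunk by the estimated
#' proportion of their variance due to finite marker sampling (a
#' regression-style correction assuming genotyped and causal loci share
#' their frequency spectrum); unadjusted and adjusted matrices are normally
#' nearly identical.
#'
#' @param panel A [genotype_panel()].
#' @param ids Optional subset of individual ids.
#' @param adjust Apply the sampling-error adjustment (default `FALSE`).
#' @param freqs Optional allele frequencies (defaults to observed).
#' @param drop_monomorphic Silently drop markers monomorphic in the chosen
#'   individuals instead of raising an error.
#' @return A symmetric matrix with individual ids as dimnames; attributes
#'   `F_hat` (per-individual inbreeding) and `n_markers`.
#' @export
compute_grm <- function(panel, ids = NULL, adjust = FALSE, freqs = NULL,
                        drop_monomorphic = FALSE) {
  G <- panel$geno
  if (!is.null(ids)) G <- G[as.character(ids), , drop = FALSE]
  p <- freqs %||% (colMeans(G, na.rm = TRUE) / 2)
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono)) {
    if (!drop_monomorphic)
      stopf("%d monomorphic markers included in GRM", sum(mono))
    G <- G[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  n <- nrow(G); m <- ncol(G)

  denom <- 2 * p * (1 - p)
  X <- sweep(G, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(denom), "/")
  miss <- is.na(X)
  if (any(miss)) {
    X[miss] <- 0
    obs <- (!miss) * 1
    counts <- tcrossprod(obs)        # markers observed in both individuals
    A <- tcrossprod(X) / pmax(counts, 1)
  } else {
    A <- tcrossprod(X) / m
  }

  # diagonal: 1 + F^ (differs from mean x_std^2 in its middle term)
  Fmat <- (G^2 - G * rep(1 + 2 * p, each = n) + rep(2 * p^2, each = n)) /
    rep(denom, each = n)
  F_hat <- rowMeans(Fmat, na.rm = TRUE)
  diag(A) <- 1 + F_hat

  if (adjust) {
    off <- A[lower.tri(A)]
    v_obs <- var(off)
    v_samp <- mean(1 / pmax(if (any(miss)) counts[lower.tri(counts)] else m, 1))
    beta <- max(0, 1 - v_samp / max(v_obs, v_samp))
    A[lower.tri(A)] <- off * beta
    A[upper.tri(A)] <- t(A)[upper.tri(A)]
    attr(A, "adjust_beta") <- beta
  }
  dimnames(A) <- list(rownames(G), rownames(G))
  attr(A, "F_hat") <- setNames(F_hat, rownames(G))
  attr(A, "n_markers") <- m
  A
}

#' Pedigree numerator relationship matrix
#'
#' Standard tabular method: `A[i,j] = (A[sire(i),j] + A[dam(i),j]) / 2` and
#' `A[i,i] = 1 + A[sire(i), dam(i)] / 2`.
#'
#' @param pedigree Pedigree `data.frame` (`id`, `sire`, `dam`).
#' @return Symmetric relationship matrix with ids as dimnames.
#' @export
pedigree_nrm <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  ids <- as.character(ped$id)
  idx <- setNames(seq_len(n), ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    si <- if (is.na(s)) 0L else idx[[as.character(s)]]
    di <- if (is.na(d)) 0L else idx[[as.character(d)]]
    if (i > 1) {
      prev <- seq_len(i - 1L)
      as_ <- if (si > 0) A[si, prev] else 0
      ad_ <- if (di > 0) A[di, prev] else 0
      A[i, prev] <- (as_ + ad_) / 2
      A[prev, i] <- A[i, prev]
    }
    A[i, i] <- 1 + (if (si > 0 && di > 0) A[si, di] / 2 else 0)
  }
  A
}

#' Write / read a GRM as GCTA-style text triplets
#'
#' `<prefix>.grm` holds one row per pair `i j n_markers value` (lower
#' triangle including diagonal); `<prefix>.grm.id` the individual ids.
#'
#' @param A Relatedness matrix with dimnames.
#' @param prefix Path prefix.
#' @return The file paths, invisibly; `read_grm()` returns the matrix.
#' @export
write_grm <- function(A, prefix) {
  ids <- rownames(A)
  n <- nrow(A)
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  m <- attr(A, "n_markers") %||% NA_integer_
  d <- data.frame(i = i, j = j, m = m, a = A[cbind(i, j)])
  data.table::fwrite(d, paste0(prefix, ".grm"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(fam = 1, id = ids), paste0(prefix, ".grm.id"),
                     sep = "\t", col.names = FALSE)
  invisible(paste0(prefix, c(".grm", ".grm.id")))
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  d <- data.table::fread(paste0(prefix, ".grm"),
                         col.names = c("i", "j", "m", "a"))
  ids <- data.table::fread(paste0(prefix, ".grm.id"))[[2]]
  n <- max(d$i)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(d$i, d$j)] <- d$a
  A[cbind(d$j, d$i)] <- d$a
  attr(A, "n_markers") <- d$m[1]
  A
}
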
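#' Greedy selection of a genotyping reference panel
#'
#' Iteratively selects the set of individuals that maximises the summed
#' proportion of population genetic variance captured, `sum(p)` with
#' `p = A_sel^{-1} c_sel`, where `A_sel` is the relationship matrix among
#' the selected individuals and `c_sel` their mean relationship to all
#' individuals. At each step the candidate whose inclusion maximises the
#' objective is added; ties break by id order, and candidates that would
#' make `A_sel` singular are skipped with a warning.
#'
#' @param A Relationship matrix (e.g. [pedigree_nrm()]), positive definite,
#'   ids in dimnames.
#' @param m Number of individuals to select (`m <= nrow(A)`).
#' @return Character vector of selected ids, with the objective after each
#'   addition in attribute `objective`.
#' @export
select_reference_panel <- function(A, m) {
  n <- nrow(A)
  if (m > n) stopf("m = %d exceeds population size %d", m, n)
  ids <- rownames(A) %||% as.character(seq_len(n))
  cvec <- rowMeans(A)
  sel <- integer(0)
  obj <- numeric(m)
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(n), sel)
    best <- -Inf; best_i <- NA_integer_
    for (i in cand) {
      trial <- c(sel, i)
      val <- tryCatch(sum(solve(A[trial, trial, drop = FALSE], cvec[trial])),
                      error = function(e) NA_real_)
      if (is.na(val)) next
      if (val > best + 1e-12) { best <- val; best_i <- i }
    }
    if (is.na(best_i)) {
      warnf("no non-singular candidate at step %d; selection stopped early", step)
      obj <- obj[seq_len(step - 1L)]
      break
    }
    sel <- c(sel, best_i)
    obj[step] <- best
  }
  structure(ids[sel], objective = obj)
}
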
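# Piecewise-linear chromosome genetic maps used by the simulator.
#
# Crossover density along a chromosome is uniform except within a
# subtelomeric window at each end, where it is multiplied by `factor`
# (used to give males elevated crossover rates near chromosome ends).
# The cumulative map is piecewise linear in bp and normalised to the
# requested total cM length.

chrom_map_nodes <- function(length_bp, total_cm, subtel_factor = 1,
                            subtel_window_bp = 0) {
  w <- min(subtel_window_bp, length_bp / 2)
  if (subtel_factor == 1 || w <= 0) {
    bp <- c(0, length_bp)
    cm <- c(0, total_cm)
  } else {
    bp <- c(0, w, length_bp - w, length_bp)
    dens <- c(subtel_factor, 1, subtel_factor)
    seg <- diff(bp) * dens
    cm <- c(0, cumsum(seg)) * total_cm / sum(seg)
  }
  list(bp = bp, cm = cm, length_bp = length_bp, total_cm = total_cm)
}

map_cm_at_bp <- function(nodes, bp) {
  approx(nodes$bp, nodes$cm, xout = bp, rule = 2)$y
}

map_bp_at_cm <- function(nodes, cm) {
  approx(nodes$cm, nodes$bp, xout = cm, rule = 2)$y
}

# Build the per-sex list of chromosome map node sets for a config.
config_maps <- function(config) {
  lapply(c(M = "M", F = "F"), function(s) {
    cms <- if (s == "M") config$map_male_cm else config$map_female_cm
    fac <- if (s == "M") config$male_subtel_factor else 1
    lapply(seq_len(config$n_chromosomes), function(c)
      chrom_map_nodes(config$chromosome_lengths_bp[c], cms[c],
                      fac, config$subtel_window_bp))
  })
}

#' Draw crossover counts and positions for one meiosis
#'
#' Simulates crossovers on every chromosome for a single gamete. Counts
#' follow the obligate model `1 + Poisson((E_c - 1) * t)` where `E_c` is the
#' chromosome's expected count (cM/100) and `t` scales the non-obligate part
#' to an individual's latent rate, or plain `Poisson(E_c * t)` without
#' obligate crossing over. With `nu = 1` positions are uniform on the cM
#' scale; with `nu != 1` a stationary gamma-renewal process with shape `nu`
#' generates positions (crossover interference), and the count is whatever
#' the renewal process yields.
#'
#' @param maps List of chromosome map node sets (one per chromosome).
#' @param t Individual scaling of the non-obligate expected count.
#' @param obligate Logical; obligate crossover model.
#' @param nu Gamma-renewal shape (1 = no interference).
#' @return List with `counts` (integer per chromosome) and `positions_bp`
#'   (list of strictly increasing bp positions per chromosome).
#' @export
sim_meiosis <- function(maps, t = 1, obligate = TRUE, nu = 1) {
  n_chr <- length(maps)
  counts <- integer(n_chr)
  pos <- vector("list", n_chr)
  for (c in seq_len(n_chr)) {
    L <- maps[[c]]$total_cm
    if (nu == 1) {
      k <- if (obligate) {
        1L + rpois(1L, max(0, (L / 100 - 1) * max(0, t)))
      } else {
        rpois(1L, max(0, L / 100 * max(0, t)))
      }
      cm <- sort(runif(k, 0, L))
    } else {
      # with interference the renewal process governs the count directly;
      # near-regular spacing makes crossover-free chromosomes rare without
      # imposing an obligate event
      cm <- gamma_renewal_positions(L * max(0, t), nu)
      if (t > 0) cm <- cm / t  # map back onto the cM axis
      k <- length(cm)
    }
    bp <- unique(round(map_bp_at_cm(maps[[c]], cm)))
    counts[c] <- length(bp)
    pos[[c]] <- sort(bp)
  }
  list(counts = counts, positions_bp = pos)
}

# Stationary gamma-renewal event positions on [0, L] cM with mean
# inter-event distance 100 cM and shape nu. The first event is drawn from
# the equilibrium forward-recurrence distribution.
gamma_renewal_positions <- function(L, nu) {
  if (L <= 0) return(numeric(0))
  rate <- nu / 100
  # forward recurrence time of a gamma renewal process: mixture; sample by
  # length-biased trick: X * U with X ~ length-biased gamma = Gamma(nu+1, rate)
  x0 <- stats::rgamma(1, shape = nu + 1, rate = rate) * runif(1)
  pos <- numeric(0)
  x <- x0
  while (x <= L) {
    pos <- c(pos, x)
    x <- x + stats::rgamma(1, shape = nu, rate = rate)
  }
  pos
}
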
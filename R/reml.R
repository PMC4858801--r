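# REML machinery for animal models of per-gamete crossover counts.
#
# The models used here share one shape: the response is measured per gamete,
# every random effect (additive genetic, permanent environment, regional
# genomic terms) is defined at the level of the individual in which meiosis
# occurred, and fixed covariates (sex, inbreeding, SNP genotype) are
# individual-level. The likelihood then factorises exactly into
#   (i)  within-individual contrasts, which carry only residual variance,
#   (ii) individual means, whose covariance is  sum_k s_k K_k + s_e D
# with D = diag(1/n_i). Restricted likelihood is maximised over the variance
# components on this reduced (q x q) scale, which makes repeated-measures
# animal models cheap even for thousands of gametes. A dense N x N fallback
# (reml_dense) covers designs with gamete-level fixed effects.

# Collapse y/W to individual level. W must be constant within individual.
.collapse_design <- function(y, id, W) {
  f <- factor(id)
  q <- nlevels(f)
  ni <- as.numeric(table(f))
  M <- as.numeric(rowsum(y, f) / ni)
  SSW <- sum((y - M[as.integer(f)])^2)
  first <- match(levels(f), f)
  W_ind <- W[first, , drop = FALSE]
  # verify constancy of fixed covariates within individual
  if (nrow(W) > q) {
    chk <- abs(W - W_ind[as.integer(f), , drop = FALSE])
    if (max(chk) > 1e-8)
      stopf("fixed covariates must be constant within individual for the collapsed fit")
  }
  list(f = f, q = q, ni = ni, M = M, SSW = SSW, W = W_ind,
       N = length(y), levels = levels(f))
}

# Negative restricted log-likelihood (up to a constant) on the collapsed
# scale. par = c(variance of each K, residual variance).
.make_collapsed_nll <- function(cd, Klist) {
  k <- length(Klist)
  function(par) {
    sig <- par[seq_len(k)]; se <- par[k + 1L]
    if (se <= 0 || any(sig < 0)) return(1e10)
    Sigma <- diag(se / cd$ni, cd$q)
    for (j in seq_len(k)) Sigma <- Sigma + sig[j] * Klist[[j]]
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ld <- 2 * sum(log(diag(R)))
    Wt <- backsolve(R, cd$W, transpose = TRUE)
    Mt <- backsolve(R, cd$M, transpose = TRUE)
    XtX <- crossprod(Wt)
    bc <- tryCatch(solve(XtX, crossprod(Wt, Mt)), error = function(e) NULL)
    if (is.null(bc)) return(1e10)
    r <- Mt - Wt %*% bc
    ldX <- as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
    0.5 * ((cd$N - cd$q) * log(se) + cd$SSW / se + ld + ldX + sum(r^2))
  }
}

# Covariance of variance-component estimates from the numerical Hessian.
# Components sitting on their lower bound make the Hessian singular; their
# rows/columns are zeroed (a boundary estimate has no interior curvature)
# and the free block is inverted, falling back to a pseudo-inverse.
.hessian_vcov <- function(H, par, lower) {
  p <- length(par)
  out <- matrix(NA_real_, p, p)
  if (is.null(H) || any(!is.finite(H))) return(out)
  free <- par > lower + 1e-8 * pmax(1, abs(par))
  out[] <- 0
  if (any(free)) {
    Hf <- H[free, free, drop = FALSE]
    Vf <- tryCatch(solve(Hf), error = function(e) {
      s <- svd(Hf)
      pos <- s$d > max(s$d) * 1e-10
      s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
        t(s$u[, pos, drop = FALSE])
    })
    out[free, free] <- Vf
  }
  out
}

# Align a covariance matrix (or the string "identity") to individual levels.
.align_K <- function(K, levels, name) {
  q <- length(levels)
  if (is.character(K) && identical(K, "identity")) return(diag(1, q))
  if (!is.matrix(K)) stopf("random effect '%s' must be a matrix or \"identity\"", name)
  if (!is.null(dimnames(K)[[1]])) {
    missing <- setdiff(levels, rownames(K))
    if (length(missing))
      stopf("relationship matrix '%s' lacks individuals: %s", name,
            paste(head(missing, 5), collapse = ", "))
    K <- K[levels, levels]
  } else if (nrow(K) != q) {
    stopf("unnamed relationship matrix '%s' must be %d x %d", name, q, q)
  }
  # guard non-positive-definiteness with a minimal ridge
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) {
    ridge <- abs(ev_min) + 1e-6
    K <- K + diag(ridge, nrow(K))
    attr(K, "ridge") <- ridge
  }
  K
}

#' REML fit of a repeated-measures animal model (collapsed scale)
#'
#' Low-level engine behind [fit_animal_model()]. All random effects are
#' individual-level with covariance matrices in `Klist`; the residual acts
#' at the observation (gamete) level.
#'
#' @param y Numeric response per observation.
#' @param id Individual of each observation.
#' @param W Fixed-effect model matrix (constant within individual).
#' @param Klist Named list of covariance matrices (or `"identity"`).
#' @param start Optional starting variances.
#' @param reltol Relative convergence tolerance.
#' @return List with variance components, their covariance matrix, GLS
#'   fixed effects, restricted log-likelihood (up to a model-family
#'   constant) and convergence information.
#' @export
reml_fit <- function(y, id, W = NULL, Klist = list(), start = NULL,
                     reltol = 1e-10) {
  if (is.null(W)) W <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  keep <- complete.cases(y, id, W)
  y <- y[keep]; id <- id[keep]; W <- W[keep, , drop = FALSE]
  cd <- .collapse_design(y, id, W)
  Ks <- lapply(seq_along(Klist), function(j)
    .align_K(Klist[[j]], cd$levels, names(Klist)[j] %||% paste0("K", j)))
  names(Ks) <- names(Klist)
  k <- length(Ks)
  nll <- .make_collapsed_nll(cd, Ks)

  vy <- var(cd$M)
  if (!is.finite(vy) || vy <= 0) vy <- max(var(y), 1e-6)
  if (is.null(start)) start <- c(rep(vy / (2 * max(1, k)), k), vy / 2)
  lower <- c(rep(0, k), vy * 1e-8)
  opt <- nlminb(start, nll, lower = lower,
                control = list(rel.tol = reltol, iter.max = 500, eval.max = 1000))
  if (opt$convergence != 0)
    warnf("REML iteration did not converge cleanly (code %d: %s)",
          opt$convergence, opt$message)

  par <- opt$par
  H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  comp_names <- c(names(Ks), "residual")
  vcov_par <- .hessian_vcov(H, par, lower)
  dimnames(vcov_par) <- list(comp_names, comp_names)

  # GLS fixed effects at the optimum
  sig <- par[seq_len(k)]; se <- par[k + 1L]
  Sigma <- diag(se / cd$ni, cd$q)
  for (j in seq_len(k)) Sigma <- Sigma + sig[j] * Ks[[j]]
  R <- chol(Sigma)
  Wt <- backsolve(R, cd$W, transpose = TRUE)
  Mt <- backsolve(R, cd$M, transpose = TRUE)
  XtX <- crossprod(Wt)
  vcov_b <- solve(XtX)
  b <- drop(vcov_b %*% crossprod(Wt, Mt))
  names(b) <- colnames(W)

  boundary <- par[seq_len(k)] < vy * 1e-6
  list(sigma = setNames(par, comp_names),
       vcov_sigma = vcov_par,
       beta = b, vcov_beta = vcov_b,
       logLik = -opt$objective,
       converged = opt$convergence == 0,
       boundary = setNames(c(boundary, FALSE), comp_names),
       n_obs = cd$N, n_ind = cd$q,
       collapsed = cd, Klist = Ks, chol_Sigma = R)
}

#' Dense REML for models with observation-level fixed effects
#'
#' General (N x N) restricted maximum likelihood used when fixed covariates
#' vary within individual (e.g. parent age at each meiosis). `Vlist`
#' contains full observation-level covariance contributors (already
#' `Z K Z'`); an identity residual is added automatically.
#'
#' @param y Response vector.
#' @param X Fixed-effect model matrix.
#' @param Vlist Named list of N x N covariance contributors.
#' @inheritParams reml_fit
#' @return As [reml_fit()] (without collapse-specific elements).
#' @export
reml_dense <- function(y, X, Vlist = list(), start = NULL, reltol = 1e-10) {
  N <- length(y)
  k <- length(Vlist)
  nll <- function(par) {
    sig <- par[seq_len(k)]; se <- par[k + 1L]
    if (se <= 0 || any(sig < 0)) return(1e10)
    V <- diag(se, N)
    for (j in seq_len(k)) V <- V + sig[j] * Vlist[[j]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ld <- 2 * sum(log(diag(R)))
    Xt <- backsolve(R, X, transpose = TRUE)
    yt <- backsolve(R, y, transpose = TRUE)
    XtX <- crossprod(Xt)
    b <- solve(XtX, crossprod(Xt, yt))
    r <- yt - Xt %*% b
    0.5 * (ld + as.numeric(determinant(XtX, TRUE)$modulus) + sum(r^2))
  }
  vy <- var(y)
  if (is.null(start)) start <- c(rep(vy / (2 * max(1, k)), k), vy / 2)
  opt <- nlminb(start, nll, lower = c(rep(0, k), vy * 1e-8),
                control = list(rel.tol = reltol, iter.max = 500, eval.max = 1000))
  par <- opt$par
  comp_names <- c(names(Vlist), "residual")
  H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  vcov_par <- if (!is.null(H)) tryCatch(solve(H), error = function(e)
    matrix(NA_real_, k + 1, k + 1)) else matrix(NA_real_, k + 1, k + 1)
  dimnames(vcov_par) <- list(comp_names, comp_names)
  list(sigma = setNames(par, comp_names), vcov_sigma = vcov_par,
       logLik = -opt$objective, converged = opt$convergence == 0)
}
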